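# Feature-level synthetic data with a known ground-truth scoring
# structure, for model and selection tests.
#
# Points for level l are placed along the true hyperplane normal so that
# their signed distance falls in level l's band (the inverse image of
# [p_{l-1}, p_l) through the sigmoid bounding); within a band the distance
# is drawn from a normal centred mid-band truncated to the band's central
# region (default: the middle half, sd = a quarter of that region), giving
# the unimodal, clearly separated per-level clusters seen in clinical
# feature distributions rather than a uniform fill. The edge margin is
# structural: rating scales assign a level only where the rater is
# confident, so noiseless data carry no boundary-hugging cases, and the
# noiseless table must remain exactly recoverable by a refit model --
# a point placed on a demarcation boundary would be unclassifiable by
# construction. Outer levels extend their band by one neighbouring band
# width. Isotropic Gaussian feature noise is added afterwards; its
# component along the (unit) normal perturbs the signed distance with the
# same sd.

#' Specification for the feature-level generator
#'
#' @param n_per_level integer vector of subjects per level, starting at
#'   level 0 (length up to 5; zeros allowed).
#' @param w true hyperplane normal (defaults to the unit-normalized
#'   all-ones direction over `n_features`).
#' @param c true offset.
#' @param p true demarcation values of the bounded distance (must satisfy
#'   the model constraints).
#' @param noise isotropic feature noise standard deviation.
#' @param n_features number of feature columns when `w` is not given.
#' @param feature_names column names (default `F1`, `F2`, ...).
#' @param base baseline feature vector the points are offset from.
#' @param edge_margin fraction of each band kept clear of points on either
#'   side (default 0.25: points occupy the central half of the band), so
#'   that the noiseless table is exactly recoverable.
#' @param bl,bu score bounds.
#' @return list of class `feature_gen_spec`.
#' @export
feature_gen_spec <- function(n_per_level = c(10, 10, 10),
                             w = NULL, c = 0, p = c(0.5, 1.5, 2.5, 3.5),
                             noise = 0, n_features = 3,
                             feature_names = NULL, base = NULL,
                             edge_margin = 0.25, bl = -0.5, bu = 4.5) {
  if (is.null(w)) w <- rep(1, n_features) / sqrt(n_features)
  n_features <- length(w)
  feature_names <- feature_names %||% paste0("F", seq_len(n_features))
  base <- base %||% rep(0, n_features)
  stopifnot(length(feature_names) == n_features,
            length(base) == n_features,
            length(n_per_level) >= 1, length(n_per_level) <= 5,
            all(n_per_level >= 0), any(n_per_level > 0), noise >= 0,
            edge_margin >= 0, edge_margin < 0.5)
  params <- scorer_params(w, c, p, bl, bu)  # validates the constraint set
  structure(list(n_per_level = n_per_level, w = w, c = c, p = p,
                 noise = noise, feature_names = feature_names,
                 base = base, edge_margin = edge_margin,
                 bl = bl, bu = bu, params = params),
            class = "feature_gen_spec")
}

# signed-distance band limits per level 0..4
level_bands <- function(spec) {
  d <- inverse_bounded_distance(spec$p, spec$bl, spec$bu)
  lo <- c(d[1] - (d[2] - d[1]), d)
  hi <- c(d, d[4] + (d[4] - d[3]))
  cbind(lo = lo, hi = hi)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic feature table
#'
#' @param spec a [feature_gen_spec].
#' @param seed optional RNG seed (set for reproducibility).
#' @return list with `table` (data.frame: `subject_id`, `rated_level`,
#'   `group`, feature columns) and `truth` (generating level, noiseless
#'   signed distance `xhp`, the true `params`, and the band matrix).
#' @export
generate_features <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "feature_gen_spec"))
  if (!is.null(seed)) set.seed(seed)
  bands <- level_bands(spec)
  levels_present <- which(spec$n_per_level > 0) - 1L
  wn <- sqrt(sum(spec$w^2))
  what <- spec$w / wn
  if (any(bands[, "hi"] <= bands[, "lo"]))
    abort_gs("empty signed-distance band: check p", "gaitscore_model_error")

  rows <- list(); lev <- integer(0); xhp <- numeric(0)
  for (l in levels_present) {
    n <- spec$n_per_level[l + 1L]
    lo <- bands[l + 1L, "lo"]; hi <- bands[l + 1L, "hi"]
    m <- spec$edge_margin * (hi - lo)
    lo <- lo + m; hi <- hi - m
    t <- rtruncnorm1(n, (lo + hi) / 2, (hi - lo) / 4, lo, hi)
    # place x so that w.x + c = t, then add isotropic noise
    u <- (t - spec$c - sum(spec$w * spec$base)) / wn
    X <- matrix(rep(spec$base, each = n), n) + outer(u, what)
    if (spec$noise > 0)
      X <- X + matrix(stats::rnorm(n * ncol(X), 0, spec$noise), n)
    rows[[length(rows) + 1L]] <- X
    lev <- c(lev, rep(l, n)); xhp <- c(xhp, t)
  }
  X <- do.call(rbind, rows)
  colnames(X) <- spec$feature_names
  table <- data.frame(
    subject_id = sprintf("S%03d", seq_len(nrow(X))),
    rated_level = as.integer(lev),
    group = ifelse(lev == 0, "healthy", "pd"),
    X, stringsAsFactors = FALSE, check.names = FALSE)
  list(table = table,
       truth = list(level = as.integer(lev), xhp = xhp,
                    params = spec$params, bands = bands,
                    band_width = mean(diff(
                      inverse_bounded_distance(spec$p, spec$bl, spec$bu)))))
}
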