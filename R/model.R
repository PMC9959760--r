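# The bounded parallel-hyperplane scoring model.
#
# Severity levels 0..4 are separated by four parallel hyperplanes
# w'x + c = d_i in feature space. The signed distance xhp = w'x + c is
# squashed by a sigmoid into yrd in (bl, bu) = (-0.5, 4.5), and a continuous
# piecewise-linear map sends the demarcation values p1..p4 (the yrd values
# at the hyperplanes) to 0.5, 1.5, 2.5 and 3.5, so that rounding the final
# score recovers the ordinal level while the fractional part quantifies
# severity within a level. Only (w, c, p) is ever stored or trained; the
# (W, C, D) form is equivalent and never materialized.

#' Scorer parameters
#'
#' Bundle of coefficients for the nonlinear severity scorer: feature
#' weights `w`, offset `c`, demarcation values `p = (p1, p2, p3, p4)` and
#' score bounds `bl`, `bu`. The demarcations must satisfy
#' `p1 - bl >= 0`, `p[i+1] > p[i]` and `bu - p4 >= 0`.
#'
#' @param w numeric weight vector (one entry per model feature).
#' @param c scalar offset.
#' @param p numeric length-4 vector of demarcation values of the bounded
#'   distance at the four hyperplanes.
#' @param bl,bu lower and upper score bounds; the UPDRS gait task uses
#'   -0.5 and 4.5 so that rounded scores cover levels 0..4.
#' @param features optional character vector naming (and ordering) the
#'   features the model consumes.
#' @param validate set `FALSE` to skip the constraint check.
#' @return an object of class `scorer_params`.
#' @seealso [check_constraints()], [score_features()]
#' @export
scorer_params <- function(w, c = 0, p = c(0.5, 1.5, 2.5, 3.5),
                          bl = -0.5, bu = 4.5, features = NULL,
                          validate = TRUE) {
  if (!is.null(features) && length(features) != length(w))
    abort_gs("length(features) must equal length(w)", "gaitscore_model_error")
  obj <- structure(
    list(w = as.numeric(w), c = as.numeric(c)[1], p = as.numeric(p),
         bl = as.numeric(bl)[1], bu = as.numeric(bu)[1],
         features = features),
    class = "scorer_params")
  if (validate) {
    viol <- check_constraints(obj)
    if (length(viol))
      abort_gs(paste0("parameter constraints violated: ",
                      paste(viol, collapse = "; ")),
               "gaitscore_model_error")
  }
  obj
}

#' @export
print.scorer_params <- function(x, ...) {
  cat("<scorer_params>\n")
  if (!is.null(x$features))
    cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat("  w:", paste(signif(x$w, 6), collapse = ", "), "\n")
  cat("  c:", signif(x$c, 6), "\n")
  cat("  p:", paste(signif(x$p, 6), collapse = ", "),
      sprintf("  (bounds %.1f, %.1f)\n", x$bl, x$bu))
  invisible(x)
}

#' Check the demarcation constraints
#'
#' Verifies `p1 - bl >= 0`, `p(i+1) - p(i) > 0` for i = 1..3 and
#' `bu - p4 >= 0`, reporting every violated inequality.
#'
#' @param params a [scorer_params] (or a bare list with `p`, `bl`, `bu`).
#' @return character vector of violated inequalities; `character(0)` when
#'   all constraints hold.
#' @export
check_constraints <- function(params) {
  p <- params$p; bl <- params$bl; bu <- params$bu
  out <- character(0)
  if (length(p) != 4) return("p must have length 4")
  if (!(p[1] - bl >= 0)) out <- c(out, "p1 - bl >= 0")
  for (i in 1:3)
    if (!(p[i + 1] - p[i] > 0))
      out <- c(out, sprintf("p%d - p%d > 0", i + 1, i))
  if (!(bu - p[4] >= 0)) out <- c(out, "bu - p4 >= 0")
  out
}

#' Signed distance to the hyperplane family
#'
#' `xhp = w'x + c`. The stored `w` already absorbs the `1/||W||`
#' normalization, so this is a plain affine map.
#'
#' @param x numeric vector of feature values in `params$features` order, or
#'   a matrix with one row per observation.
#' @param params a [scorer_params].
#' @return numeric vector of signed distances.
#' @export
signed_distance <- function(x, params) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(params$w))
    abort_gs(sprintf("expected %d feature(s), got %d",
                     length(params$w), ncol(x)), "gaitscore_model_error")
  drop(x %*% params$w) + params$c
}

#' Sigmoid-bounded distance
#'
#' Maps the signed distance into the open interval `(bl, bu)`:
#' `yrd = (bu - bl) / (1 + exp(-(xhp - (bu + bl)/2))) + bl`, i.e. with the
#' default bounds `yrd = 5 / (1 + exp(-xhp + 2)) - 0.5`.
#'
#' @param xhp numeric vector of signed distances.
#' @param bl,bu score bounds.
#' @return numeric vector, strictly increasing in `xhp`.
#' @export
bounded_distance <- function(xhp, bl = -0.5, bu = 4.5) {
  (bu - bl) / (1 + exp(-(xhp - (bu + bl) / 2))) + bl
}

#' Invert the sigmoid bounding
#'
#' Returns the signed distance whose bounded image is `yrd`; used to place
#' points exactly on a demarcation hyperplane.
#'
#' @param yrd values strictly inside `(bl, bu)`.
#' @inheritParams bounded_distance
#' @export
inverse_bounded_distance <- function(yrd, bl = -0.5, bu = 4.5) {
  if (any(yrd <= bl | yrd >= bu))
    abort_gs("yrd must lie strictly inside (bl, bu)", "gaitscore_model_error")
  (bu + bl) / 2 - log((bu - bl) / (yrd - bl) - 1)
}

#' Continuous piecewise score
#'
#' Rescales the bounded distance segment-wise so that the demarcation
#' values `p1..p4` map to 0.5, 1.5, 2.5 and 3.5 exactly: with boundaries
#' `(bl, p1, p2, p3, p4, bu)` and `j` the segment index of `yrd`,
#' `y = (yrd - lower_j) / (upper_j - lower_j) + bl + j`. The map is
#' continuous and strictly increasing; with evenly spaced demarcations
#' `p = (0.5, 1.5, 2.5, 3.5)` it reduces to the identity.
#'
#' @param yrd numeric vector in `(bl, bu)` (demarcation values included).
#' @param params a [scorer_params].
#' @return numeric vector of continuous scores in `(bl, bu)`.
#' @export
piecewise_score <- function(yrd, params) {
  bl <- params$bl; bu <- params$bu
  if (any(yrd < bl | yrd > bu))
    abort_gs("yrd outside [bl, bu]", "gaitscore_model_error")
  bounds <- c(bl, params$p, bu)
  # segment index 0..4; yrd == p_i assigned to either side gives the same y
  j <- findInterval(yrd, bounds, rightmost.closed = TRUE,
                    left.open = TRUE, all.inside = TRUE) - 1L
  lower <- bounds[j + 1L]; upper <- bounds[j + 2L]
  (yrd - lower) / (upper - lower) + bl + j
}

#' Score feature vectors
#'
#' Full forward pass of the nonlinear model: signed hyperplane distance,
#' sigmoid bounding, then the piecewise rescaling. Strictly increasing in
#' `w'x + c`, with values in `(bl, bu)`.
#'
#' @inheritParams signed_distance
#' @return numeric vector of continuous severity scores.
#' @export
score_features <- function(x, params) {
  piecewise_score(bounded_distance(signed_distance(x, params),
                                   params$bl, params$bu), params)
}

#' Round a continuous score to an ordinal level
#'
#' Nearest integer in 0..4; exact half-points round towards the higher
#' severity (2.5 becomes 3).
#'
#' @param y numeric vector of continuous scores in `(-0.5, 4.5)`.
#' @return integer vector of levels.
#' @export
round_to_level <- function(y) {
  lev <- floor(y + 0.5)
  as.integer(pmin(4, pmax(0, lev)))
}
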