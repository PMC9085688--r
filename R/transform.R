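# Variable transformation: Box-Cox symmetrization followed by centring and
# scaling, so regression coefficients are standardized.

#' Box-Cox transformation with automatic shift and exponent
#'
#' Non-positive vectors are shifted by `|min(x)| + 0.01 * range(x)` first.
#' The exponent `lambda` maximizes the Box-Cox profile log-likelihood of a
#' location-scale normal model over `[-3, 3]`; the transform is
#' `((x + shift)^lambda - 1) / lambda`, or `log(x + shift)` at
#' `lambda = 0`.
#'
#' @param x Numeric vector, length >= 3, non-constant.
#' @param lambda Fix the exponent instead of estimating it.
#' @return List with `lambda`, `shift` and the transformed vector `y`.
#' @export
box_cox <- function(x, lambda = NULL) {
  if (length(x) < 3) stop("need at least 3 values", call. = FALSE)
  rng <- diff(range(x))
  if (rng == 0) stop("constant vector cannot be Box-Cox transformed",
                     call. = FALSE)
  shift <- if (min(x) <= 0) abs(min(x)) + 0.01 * rng else 0
  xs <- x + shift
  bc <- function(l) if (abs(l) < 1e-12) log(xs) else (xs^l - 1) / l
  if (is.null(lambda)) {
    n <- length(xs)
    slx <- sum(log(xs))
    prof <- function(l) {
      y <- bc(l)
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slx
    }
    lambda <- stats::optimize(prof, c(-3, 3), maximum = TRUE, tol = 1e-6)$maximum
  }
  list(lambda = lambda, shift = shift, y = bc(lambda))
}

#' Fit a standardizing transform (Box-Cox, centre, scale)
#'
#' @param x Numeric vector.
#' @param lambda Optional fixed Box-Cox exponent.
#' @return An `lg_transform` with fields `lambda`, `shift`, `centre`,
#'   `scale`; apply with [apply_transform()], invert with
#'   [invert_transform()].
#' @export
fit_transform <- function(x, lambda = NULL) {
  b <- box_cox(x, lambda = lambda)
  centre <- mean(b$y)
  scale <- stats::sd(b$y)
  if (scale <= 0) stop("degenerate scale", call. = FALSE)
  structure(list(lambda = b$lambda, shift = b$shift, centre = centre,
                 scale = scale), class = "lg_transform")
}

#' @rdname fit_transform
#' @param spec An `lg_transform`.
#' @export
apply_transform <- function(spec, x) {
  xs <- x + spec$shift
  y <- if (abs(spec$lambda) < 1e-12) log(xs) else (xs^spec$lambda - 1) / spec$lambda
  (y - spec$centre) / spec$scale
}

#' @rdname fit_transform
#' @param y Transformed values.
#' @export
invert_transform <- function(spec, y) {
  z <- y * spec$scale + spec$centre
  xs <- if (abs(spec$lambda) < 1e-12) exp(z) else (z * spec$lambda + 1)^(1 / spec$lambda)
  xs - spec$shift
}

#' Standardize a set of columns in place
#'
#' Applies [fit_transform()] to each named column and returns the
#' transformed data together with the fitted specs (needed to express
#' model effects on the original scales).
#'
#' @param data Data frame.
#' @param cols Character vector of column names.
#' @return List with `data` (tibble) and `specs` (named list of
#'   `lg_transform`).
#' @export
transform_columns <- function(data, cols) {
  data <- tibble::as_tibble(data)
  specs <- list()
  for (cl in cols) {
    sp <- fit_transform(data[[cl]])
    data[[cl]] <- apply_transform(sp, data[[cl]])
    specs[[cl]] <- sp
  }
  list(data = data, specs = specs)
}
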