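#' @importFrom rlang .data
#' @importFrom stats median quantile rnorm rpois rlnorm runif sd var
#' @importFrom stats shapiro.test var.test t.test kruskal.test pnorm pt pf
#' @importFrom stats pchisq p.adjust lm aov coef predict anova setNames
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Deterministic 31-bit string hash used to derive independent per-entity RNG
# streams from one root seed. Must stay stable across sessions/platforms, so
# it is plain integer arithmetic in doubles (all intermediates < 2^53).
#' @keywords internal
seed_stream <- function(root_seed, ...) {
  key <- paste(c(as.character(root_seed), vapply(list(...), as.character,
                                                 character(1))),
               collapse = "\r")
  h <- 17
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483563
  }
  as.integer(h + 1)  # keep strictly positive, < 2^31
}

#' @keywords internal
with_stream <- function(root_seed, ..., code) {
  withr::with_seed(seed_stream(root_seed, ...), code)
}

#' Significance stars
#'
#' Maps p-values to the star convention used in the group-comparison reports:
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.005, `****` p < 0.001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star strings (`""` for non-significant).
#' @export
significance_stars <- function(p) {
  cut(p,
      breaks = c(-Inf, 0.001, 0.005, 0.01, 0.05, Inf),
      labels = c("****", "***", "**", "*", ""),
      right = FALSE) |> as.character()
}

# Bilinearly upscale a coarse matrix to nr x nc (as two 1-D linear
# interpolations, W_r %*% coarse %*% t(W_c)); used for the smooth
# autofluorescence texture of synthetic fields.
#' @keywords internal
bilinear_upscale <- function(coarse, nr, nc) {
  interp_weights <- function(n_from, n_to) {
    pos <- seq(1, n_from, length.out = n_to)
    lo <- pmin(floor(pos), n_from - 1L)
    a <- pos - lo
    w <- matrix(0, n_to, n_from)
    w[cbind(seq_len(n_to), lo)] <- 1 - a
    w[cbind(seq_len(n_to), lo + 1L)] <- a
    w
  }
  interp_weights(nrow(coarse), nr) %*% coarse %*%
    t(interp_weights(ncol(coarse), nc))
}

#' @keywords internal
log_msg <- function(...) {
  if (isTRUE(getOption("istquant.quiet", FALSE))) return(invisible())
  message(sprintf(...))
}
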