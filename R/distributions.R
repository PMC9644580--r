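#' Parameter sampling distributions
#'
#' Constructors for the sampling distributions used in probabilistic
#' sensitivity analysis: gamma for right-skewed nonnegative costs, beta
#' for utilities bounded in \[0, 1\], Dirichlet for transition-matrix rows
#' backed by count evidence, and a degenerate fixed value. Gamma and beta
#' laws are parameterised by their mean and standard deviation and
#' converted to shape parameters by the method of moments, so the printed
#' (mean, SD) estimate is reproduced exactly.
#'
#' @param mean,sd distribution mean and standard deviation. For
#'   [gamma_from_mean_sd()] both must be positive; for
#'   [beta_from_mean_sd()] the mean must lie in (0, 1) and
#'   `sd^2 < mean * (1 - mean)` (otherwise no beta law exists).
#' @return an object of class `cad_dist` with the moments and derived
#'   shape parameters (`shape`/`scale` for gamma, `a`/`b` for beta).
#' @export
#' @examples
#' gamma_from_mean_sd(26261.18, 4908.53)  # shape ~28.6, scale ~917
#' beta_from_mean_sd(0.69, 0.12)
gamma_from_mean_sd <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("gamma mean must be > 0")
  if (!is.finite(sd) || sd <= 0) stop("gamma sd must be > 0")
  structure(
    list(kind = "gamma", mean = mean, sd = sd,
         shape = (mean / sd)^2, scale = sd^2 / mean),
    class = "cad_dist"
  )
}

#' @rdname gamma_from_mean_sd
#' @export
beta_from_mean_sd <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("beta mean must lie strictly between 0 and 1")
  }
  if (!is.finite(sd) || sd <= 0 || sd^2 >= mean * (1 - mean)) {
    stop(sprintf(
      "no beta law has mean %.4g and sd %.4g (need sd^2 < mean*(1-mean))",
      mean, sd))
  }
  k <- mean * (1 - mean) / sd^2 - 1
  structure(
    list(kind = "beta", mean = mean, sd = sd, a = mean * k, b = (1 - mean) * k),
    class = "cad_dist"
  )
}

#' @rdname gamma_from_mean_sd
#' @param counts nonnegative vector of at least two transition counts.
#' @param pseudo_count nonnegative value added to every cell (default 0),
#'   useful when some cells are empty.
#' @export
dirichlet_spec <- function(counts, pseudo_count = 0) {
  counts <- as.numeric(counts) + pseudo_count
  if (length(counts) < 2L) stop("dirichlet needs at least 2 counts")
  if (any(counts < 0)) stop("dirichlet counts must be nonnegative")
  if (sum(counts) <= 0) {
    stop("dirichlet counts sum to 0; supply a positive pseudo_count")
  }
  structure(
    list(kind = "dirichlet", counts = counts,
         mean = counts / sum(counts)),
    class = "cad_dist"
  )
}

#' @rdname gamma_from_mean_sd
#' @param value the fixed value returned by every draw.
#' @export
fixed_spec <- function(value) {
  if (!is.finite(value)) stop("fixed value must be finite")
  structure(list(kind = "fixed", mean = value, sd = 0, value = value),
            class = "cad_dist")
}

#' @export
print.cad_dist <- function(x, ...) {
  extra <- switch(x$kind,
    gamma = sprintf(" (shape %.4g, scale %.4g)", x$shape, x$scale),
    beta = sprintf(" (a %.4g, b %.4g)", x$a, x$b),
    dirichlet = sprintf(" (%d cells, n = %g)", length(x$counts), sum(x$counts)),
    "")
  if (x$kind == "dirichlet") {
    cat(sprintf("<cad_dist> dirichlet%s\n", extra))
  } else {
    cat(sprintf("<cad_dist> %s mean %.6g sd %.4g%s\n", x$kind, x$mean, x$sd, extra))
  }
  invisible(x)
}

#' Sample from a distribution spec
#'
#' Draws respect the support by construction: gamma draws are nonnegative,
#' beta draws lie in \[0, 1\], Dirichlet draws are probability vectors
#' summing to 1. RNG state is the caller's; seed upstream.
#'
#' @param spec a `cad_dist`.
#' @param n number of draws.
#' @return numeric vector of length `n`, or for a Dirichlet spec an
#'   `n x k` matrix with unit row sums.
#' @export
sample_spec <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "cad_dist"))
  switch(spec$kind,
    fixed = rep.int(spec$value, n),
    gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    beta = stats::rbeta(n, spec$a, spec$b),
    dirichlet = {
      k <- length(spec$counts)
      g <- matrix(stats::rgamma(n * k, shape = rep(spec$counts, each = n),
                                scale = 1), nrow = n)
      # zero-count cells draw exactly 0, keeping the support
      g[, spec$counts == 0] <- 0
      sw <- rowSums(g)
      if (any(sw == 0)) stop("degenerate dirichlet draw; use a pseudo_count")
      g / sw
    },
    stop("unknown distribution kind: ", spec$kind)
  )
}

#' Moments of a distribution spec
#'
#' Inverts the shape parameterisation back to (mean, sd); round-trips with
#' the constructors to full floating-point precision.
#'
#' @param spec a `cad_dist`.
#' @return named numeric vector `c(mean =, sd =)` (for a Dirichlet spec,
#'   the mean vector).
#' @export
spec_moments <- function(spec) {
  stopifnot(inherits(spec, "cad_dist"))
  switch(spec$kind,
    fixed = c(mean = spec$value, sd = 0),
    gamma = c(mean = spec$shape * spec$scale,
              sd = sqrt(spec$shape) * spec$scale),
    beta = {
      a <- spec$a; b <- spec$b
      c(mean = a / (a + b),
        sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    dirichlet = spec$mean
  )
}
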