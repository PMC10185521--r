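# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and labels
#'
#' Stable polynomial hash of the labels mixed with the master seed; the
#' result is a positive 32-bit integer so it is always a legal `set.seed()`
#' argument. Used to give every analysis / replicate its own stream.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the sub-analysis.
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, ...) {
  label <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                        character(1)), collapse = "|")
  h <- 7
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(as.numeric(master)) * 48271 + h) %% 2147483646 + 1)
}

# weighted quantile (step interpolation of the weighted ECDF)
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

weighted_sd <- function(x, w) {
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

# two-sided normal p-value, clamped into (0, 1]
z_pval <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# two-sided t p-value, clamped into (0, 1]
t_pval <- function(t, df) {
  p <- 2 * stats::pt(-abs(t), df = df)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

stop_bimr <- function(...) stop(..., call. = FALSE)
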