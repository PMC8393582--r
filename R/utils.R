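# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residual-sum-of-squares AIC for a linear model
#'
#' Constant-free AIC used for all model comparison in this package:
#' `n * log(RSS / n) + 2 * k`, where `k` counts the estimated regression
#' coefficients (including the intercept).  The additive constant and the
#' residual-variance parameter are dropped; only AIC *differences* between
#' models fitted to the same response are meaningful.
#'
#' @param fit an `lm` fit.
#' @return numeric AIC value.
#' @export
aic_rss <- function(fit) {
  stopifnot(inherits(fit, "lm"))
  r <- stats::residuals(fit)
  n <- length(r)
  rss <- sum(r^2)
  n * log(rss / n) + 2 * length(stats::coef(fit))
}

## validation helpers --------------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name, open = TRUE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("`%s` must be a single value %s", name,
                 if (open) "in (0, 1)" else "in [0, 1]"), call. = FALSE)
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
         call. = FALSE)
  }
  as.numeric(x)
}

# derive a reproducible child seed from a parent seed and a stream label;
# kept below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587 + 1)
}

# md5 of a config list, for output-header provenance
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}
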