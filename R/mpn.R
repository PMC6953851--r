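#' @importFrom stats uniroot qnorm
NULL

## Most-probable-number estimation. Each vial inoculated with m grams of
## original material is positive with probability 1 - exp(-lambda * m)
## under a Poisson distribution of viable cells; the MLE solves the score
## equation
##   sum_i g_i m_i exp(-l m_i) / (1 - exp(-l m_i)) = sum_i (n_i - g_i) m_i
## with g_i positives out of n_i vials at amount m_i.

mpnScore <- function(lambda, m, n, g) {
  e <- exp(-lambda * m)
  sum(g * m * e / (1 - e)) - sum((n - g) * m)
}

## Observed information for log(lambda) at the MLE (where the score term
## vanishes): I(log l) = l^2 * sum_i g_i m_i^2 e^{-l m_i}/(1-e^{-l m_i})^2.
mpnLogInfo <- function(lambda, m, g) {
  e <- exp(-lambda * m)
  lambda^2 * sum(g * m^2 * e / (1 - e)^2)
}

#' Most-probable-number estimate for one dilution series
#'
#' Maximum-likelihood estimation of viable cell density (cells per gram)
#' from presence/absence outcomes across a serial dilution, with an
#' approximate 95% interval from the observed information of
#' `log(lambda)`. The estimate solves the MPN score equation by bracketed
#' root finding to a relative tolerance of 1e-8, with an initial bracket
#' of [1e-3, 1e12] cells/g expanded geometrically if required.
#'
#' Edge cases follow the likelihood: a series with no positive vial has
#' `lambda_hat = 0` (no interval); a series with every vial positive has
#' an unbounded MLE, flagged via `unbounded = TRUE` with `lambda_hat = NA`
#' and `ci_low` set to the 95% likelihood lower bound (the density at
#' which the all-positive outcome has probability 0.05).
#'
#' @param series data.frame with columns `amount_g` (grams of original
#'   material per vial, strictly decreasing), `n_vials`, `n_positive`;
#'   an optional `sample_id` column is carried through.
#' @return one-row data.frame: `sample_id`, `lambda_hat`, `ci_low`,
#'   `ci_high` (cells/g), `display` (`lambda_hat / 1e4` rounded to two
#'   decimals, the conventional reporting scale), `all_negative`,
#'   `unbounded`.
#' @examples
#' estimateMPN(data.frame(amount_g = c(0.1, 0.01, 0.001),
#'                        n_vials = 3, n_positive = c(3, 2, 0)))
#' @export
estimateMPN <- function(series) {
  need <- c("amount_g", "n_vials", "n_positive")
  stopifnot(all(need %in% names(series)))
  if (!nrow(series)) stop("empty dilution series")
  m <- as.numeric(series$amount_g)
  n <- as.numeric(series$n_vials)
  g <- as.numeric(series$n_positive)
  if (any(m <= 0)) stop("dilution amounts must be positive")
  if (any(g < 0 | g > n)) stop("n_positive must lie in [0, n_vials]")
  sid <- if ("sample_id" %in% names(series)) series$sample_id[1] else NA_character_

  res <- data.frame(sample_id = sid, lambda_hat = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    display = NA_real_, all_negative = FALSE,
                    unbounded = FALSE, stringsAsFactors = FALSE)

  if (all(g == 0)) {
    res$lambda_hat <- 0
    res$display <- 0
    res$all_negative <- TRUE
    return(res)
  }
  if (all(g == n)) {
    ## likelihood increasing in lambda: report the 95% lower bound from
    ## P(all positive | lambda) = prod (1 - exp(-lambda m))^n = 0.05
    f <- function(l) sum(n * log1p(-exp(-l * m))) - log(0.05)
    lo <- 1e-6
    while (f(lo) > 0) lo <- lo / 10
    hi <- 1
    while (f(hi) < 0) hi <- hi * 10
    res$ci_low <- uniroot(f, c(lo, hi), tol = 1e-10)$root
    res$unbounded <- TRUE
    return(res)
  }

  lo <- 1e-3
  hi <- 1e12
  while (mpnScore(lo, m, n, g) < 0 && lo > .Machine$double.xmin * 1e6) lo <- lo / 10
  while (mpnScore(hi, m, n, g) > 0 && hi < 1e300) hi <- hi * 10
  lambda <- uniroot(mpnScore, c(lo, hi), m = m, n = n, g = g,
                    tol = 1e-8 * lo, extendInt = "downX")$root
  ## polish to relative tolerance 1e-8
  lambda <- uniroot(mpnScore, c(lambda * 0.9, lambda * 1.1), m = m, n = n,
                    g = g, tol = lambda * 1e-10, extendInt = "downX")$root

  se_log <- 1 / sqrt(mpnLogInfo(lambda, m, g))
  z <- qnorm(0.975)
  res$lambda_hat <- lambda
  res$ci_low <- lambda * exp(-z * se_log)
  res$ci_high <- lambda * exp(z * se_log)
  res$display <- round(lambda / 1e4, 2)
  res
}

#' MPN estimates for every sample in a dilution table
#'
#' Applies [estimateMPN()] per `sample_id` of a dilution outcome table
#' (e.g. [dilutionData()] of a collection).
#'
#' @param dilutions data.frame with columns `sample_id`, `amount_g`,
#'   `n_vials`, `n_positive`.
#' @return data.frame with one row per sample, as in [estimateMPN()].
#' @export
estimateMPNAll <- function(dilutions) {
  stopifnot(all(c("sample_id", "amount_g", "n_vials", "n_positive") %in%
                  names(dilutions)))
  out <- lapply(split(dilutions, dilutions$sample_id)[unique(dilutions$sample_id)],
                estimateMPN)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sum of per-medium display MPN values for one sample
#'
#' The total population count of a sample (one isolation source x soil
#' combination) is the sum of the per-medium display MPN values (units of
#' 1e4 cells/g), rounded to two decimals. Media with no growth contribute
#' zero; an empty group totals zero.
#'
#' @param values numeric vector of per-medium display MPN values.
#' @return the rounded total.
#' @examples
#' totalMPN(c(7.67, 0, 3.33, 0, 0)) # 11.00
#' @export
totalMPN <- function(values) {
  if (!length(values)) return(0)
  round(sum(round(values, 2)), 2)
}

#' Summarize a sample-by-medium MPN table
#'
#' Computes, from a long table of display MPN values (one row per sample
#' and medium), the per-medium means across all samples and the per-soil
#' means of sample totals. The sample grid is completed first: a
#' sample-medium combination absent from the table counts as zero, and
#' means divide by the number of samples (not by the count of non-zero
#' cells).
#'
#' @param tab data.frame with columns `source`, `soil`, `medium`, `mpn`
#'   (display units, 1e4 cells/g). An optional `n` column of isolate
#'   counts is summed per medium and soil when present.
#' @return list with `samples` (per-sample totals), `medium_means`
#'   (named, 2-decimal), `soil_means` (named, 2-decimal means of the
#'   sample totals per soil), and `grid` (the completed sample x medium
#'   matrix of display values).
#' @export
summarizeMPN <- function(tab) {
  stopifnot(all(c("source", "soil", "medium", "mpn") %in% names(tab)))
  samples <- unique(tab[, c("source", "soil")])
  key <- paste(tab$source, tab$soil)
  skey <- paste(samples$source, samples$soil)
  grid <- matrix(0, nrow = nrow(samples), ncol = length(DZ_MEDIA),
                 dimnames = list(skey, DZ_MEDIA))
  for (i in seq_len(nrow(tab))) {
    grid[key[i], tab$medium[i]] <- tab$mpn[i]
  }
  totals <- apply(grid, 1, totalMPN)
  samples$total <- totals

  medium_means <- round(colMeans(grid), 2)
  soil_means <- round(tapply(totals, samples$soil, mean), 2)
  soil_means <- soil_means[intersect(DZ_SOILS, names(soil_means))]

  list(samples = samples, medium_means = medium_means,
       soil_means = soil_means, grid = grid)
}
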