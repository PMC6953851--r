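#' @importFrom stats aov anova qchisq cor.test var
NULL

#' One-way ANOVA on greenhouse biomass observations
#'
#' Fits the textbook one-way decomposition (via [stats::aov()]) of a dry
#' weight response on the treatment factor for one plant species, and
#' extracts the quantities the Scott-Knott procedure consumes: group
#' means, the error mean square, error degrees of freedom and the
#' (harmonic-mean) replicate count.
#'
#' @param obs biomass data.frame (`species`, `treatment`, `replicate`,
#'   response columns), e.g. [biomassData()].
#' @param species which species to analyse (`"tomato"` or `"lulo"`);
#'   ignored when `obs` has a single species or no `species` column.
#' @param response `"rdw"` or `"sdw"`.
#' @return object of class `dzAnova`: list with `k` (group count), `r`
#'   (replicates per group; harmonic mean if unbalanced), `balanced`,
#'   `F`, `mse`, `df_error`, `means` (named, by treatment), `n_per_group`.
#' @examples
#' d <- data.frame(species = "tomato",
#'                 treatment = rep(c("A", "B"), each = 3),
#'                 replicate = rep(1:3, 2), rdw = c(1, 2, 3, 4, 5, 6),
#'                 sdw = 1)
#' oneWayAnova(d, "tomato", "rdw")$F # 13.5
#' @export
oneWayAnova <- function(obs, species = NULL, response = c("rdw", "sdw")) {
  response <- match.arg(response)
  if (!is.null(species) && "species" %in% names(obs)) {
    obs <- obs[obs$species == species, , drop = FALSE]
  }
  if (!nrow(obs)) stop("no observations for the requested species")
  y <- obs[[response]]
  g <- factor(obs$treatment)
  n_per <- table(g)
  if (length(n_per) < 2) stop("one-way ANOVA needs at least 2 groups")
  if (any(n_per < 2)) {
    stop("every group needs >= 2 replicates (offending: ",
         paste(names(n_per)[n_per < 2], collapse = ", "), ")")
  }
  if (var(y) == 0) {
    ## all observations identical: SS_between = SS_within = 0, F := 0
    tab <- data.frame(check.names = FALSE,
                      `F value` = c(0, NA), `Mean Sq` = c(0, 0),
                      Df = c(length(n_per) - 1L, length(y) - length(n_per)))
    Fval <- 0
  } else {
    fit <- aov(y ~ g)
    tab <- anova(fit)
    Fval <- tab[["F value"]][1]
  }
  means <- as.numeric(tapply(y, g, mean))
  names(means) <- levels(g)
  r_h <- length(n_per) / sum(1 / as.numeric(n_per))
  structure(list(k = length(n_per),
                 r = r_h,
                 balanced = length(unique(as.numeric(n_per))) == 1,
                 F = Fval,
                 mse = tab[["Mean Sq"]][2],
                 df_error = tab[["Df"]][2],
                 means = means[order(names(means))],
                 n_per_group = as.numeric(n_per)[order(names(n_per))],
                 response = response),
            class = "dzAnova")
}

#' @export
print.dzAnova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: k = %d groups, F = %.4g, MSE = %.4g (df = %d)%s\n",
              x$k, x$F, x$mse, x$df_error,
              if (x$balanced) "" else " [unbalanced: harmonic-mean r]"))
  invisible(x)
}

## One Scott-Knott split decision on a vector of sorted means. Returns
## the accepted split index (number of means in the top part) or 0L.
skSplit <- function(means, s2_ybar, nu, alpha) {
  k <- length(means)
  if (k < 2) return(0L)
  ## maximize B0 over the k-1 ordered split points
  best_b0 <- -Inf
  best_i <- 0L
  total <- sum(means)
  t1 <- 0
  for (i in seq_len(k - 1)) {
    t1 <- t1 + means[i]
    t2 <- total - t1
    b0 <- t1^2 / i + t2^2 / (k - i) - total^2 / k
    if (b0 > best_b0 + 1e-12) {
      best_b0 <- b0
      best_i <- i
    }
  }
  if (best_b0 <= 1e-12) return(0L)
  ybar <- total / k
  sigma2_0 <- (sum((means - ybar)^2) + nu * s2_ybar) / (k + nu)
  if (sigma2_0 <= 0) return(best_i) # degenerate: no residual noise at all
  lambda <- pi / (2 * (pi - 2)) * best_b0 / sigma2_0
  crit <- qchisq(1 - alpha, df = k / (pi - 2))
  if (is.finite(crit) && lambda > crit) best_i else 0L
}

#' Scott-Knott clustering of treatment means
#'
#' Partitions the sorted treatment means of a one-way ANOVA into
#' non-overlapping groups by the Scott-Knott procedure: at each node the
#' ordered split maximizing the between-group sum of squares
#' `B0 = T1^2/k1 + T2^2/k2 - (T1+T2)^2/(k1+k2)` is tested with
#' `lambda = pi / (2 (pi - 2)) * B0 / sigma0^2`, where
#' `sigma0^2 = (sum (m_i - m)^2 + nu s2_ybar) / (k + nu)` and
#' `s2_ybar = mse / r`; the split is accepted iff `lambda` exceeds the
#' chi-square quantile at `1 - alpha` with `k / (pi - 2)` degrees of
#' freedom (evaluated with the continuous quantile function), and the
#' procedure recurses on the accepted halves.
#'
#' Groups are intervals in sorted-mean order; cluster labels `a`, `b`,
#' ... are assigned from the highest mean down.
#'
#' @param anova a `dzAnova` from [oneWayAnova()].
#' @param alpha significance level (default 0.05).
#' @return object of class `dzMeansGrouping`: data.frame with columns
#'   `treatment`, `mean`, `group` (1 = highest-mean cluster), `label`,
#'   ordered by descending mean.
#' @export
scottKnott <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "dzAnova"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  means <- sort(anova$means, decreasing = TRUE)
  s2_ybar <- anova$mse / anova$r
  nu <- anova$df_error
  k <- length(means)
  groups <- integer(k)
  nextGroup <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      counter
    }
  })
  recurse <- function(idx) {
    split_at <- skSplit(as.numeric(means[idx]), s2_ybar, nu, alpha)
    if (split_at == 0L) {
      groups[idx] <<- nextGroup()
    } else {
      recurse(idx[seq_len(split_at)])
      recurse(idx[(split_at + 1L):length(idx)])
    }
  }
  recurse(seq_len(k))
  out <- data.frame(treatment = names(means), mean = as.numeric(means),
                    group = groups, label = letters[pmin(groups, 26L)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dzMeansGrouping", "data.frame")
  out
}

#' Pearson correlation with a two-sided t test
#'
#' Product-moment correlation between two numeric vectors, with the
#' two-sided p value from the t transform on `n - 2` degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and `p`.
#' @examples
#' pearsonCorrelation(c(1, 2, 3, 4), c(2, 1, 4, 3)) # r = 0.6
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @importFrom stats sd
NULL
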