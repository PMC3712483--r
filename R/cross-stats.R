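## Statistics on cross phenotype counts: Mendelian goodness-of-fit, the
## posterior upper bound on the supergene recombination fraction, and the
## chromosomal co-location probability of the supergene loci.

#' Chi-square goodness-of-fit test for Mendelian segregation
#'
#' Pearson's statistic for observed phenotype class counts against an
#' expected segregation ratio (for a testcross at two loci, 1:1:1:1 under
#' free recombination).
#'
#' @param counts phenotype counts (see [phenotype_counts()]) or any
#'   non-negative count vector.
#' @param ratio expected ratio, one non-negative weight per class.
#' @return list with `statistic`, `df` (classes - 1) and `p_value` (upper
#'   tail).
#' @examples
#' chi2_segregation(c(0, 156, 133, 0), c(1, 1, 1, 1))  # 292.7 on 3 df
#' @export
chi2_segregation <- function(counts, ratio = rep(1, length(counts))) {
  O <- as.numeric(counts)
  if (length(ratio) != length(O))
    stop("ratio must have one entry per class")
  if (any(O < 0) || any(ratio < 0) || sum(O) <= 0 || sum(ratio) <= 0)
    stop("counts and ratio must be non-negative, with positive totals")
  E <- sum(O) * ratio / sum(ratio)
  if (any(E == 0 & O > 0))
    stop("observed counts in a class with zero expected frequency ",
         "(classes: ", paste(which(E == 0 & O > 0), collapse = ", "), ")")
  keep <- E > 0
  statistic <- sum((O[keep] - E[keep])^2 / E[keep])
  df <- length(O) - 1L
  list(statistic = statistic, df = df,
       p_value = pchisq(statistic, df, lower.tail = FALSE))
}

#' Posterior upper confidence limit on a recombination fraction
#'
#' With zero recombinants observed in `n_meioses` meioses, the likelihood of
#' the recombination fraction theta is `(1 - theta)^n`. Under a flat prior
#' truncated to `[0, 0.5]` the posterior is proportional to `(1 - theta)^n`
#' there, and the `level` upper quantile has the closed form
#' `1 - (1 - level * (1 - 0.5^(n+1)))^(1/(n+1))`.
#'
#' @param n_meioses number of informative meioses `n` (non-negative).
#' @param n_recombinant observed recombinants; only the zero-recombinant case
#'   has this closed form, other values are an error.
#' @param level posterior coverage in (0, 1), default 0.95.
#' @return list with `n_meioses`, `n_recombinant`, `confidence_level` and
#'   `upper_limit` (theta bound in `[0, 0.5]`).
#' @examples
#' recombination_upper_limit(323)   # upper limit ~ 0.0092
#' recombination_upper_limit(0)     # prior quantile 0.475
#' @export
recombination_upper_limit <- function(n_meioses, n_recombinant = 0,
                                      level = 0.95) {
  if (n_recombinant != 0)
    stop("only the zero-recombinant posterior has a closed form; got ",
         n_recombinant, " recombinants")
  if (n_meioses < 0 || level <= 0 || level >= 1)
    stop("need n_meioses >= 0 and level in (0, 1)")
  n <- n_meioses
  u <- 1 - (1 - level * (1 - 0.5^(n + 1)))^(1 / (n + 1))
  list(n_meioses = n, n_recombinant = 0, confidence_level = level,
       upper_limit = u)
}

#' Probability that several loci land on one chromosome by chance
#'
#' Probability that, when `m_loci` loci are assigned independently and
#' uniformly to `n_chromosomes` chromosomes, at least one chromosome
#' receives `k_min` or more of them. Computed exactly by dynamic programming
#' over the multinomial occupancy distribution (complement: all chromosomes
#' receive fewer than `k_min`).
#'
#' @param n_chromosomes haploid chromosome number (22 for *C. nemoralis*).
#' @param m_loci number of loci assigned.
#' @param k_min cluster size of interest.
#' @return probability in `[0, 1]`.
#' @examples
#' supergene_cluster_probability(22, 8, 5)  # ~2e-4
#' @export
supergene_cluster_probability <- function(n_chromosomes, m_loci, k_min) {
  if (n_chromosomes < 1 || m_loci < 1 || k_min < 1 || k_min > m_loci)
    stop("need n_chromosomes >= 1 and 1 <= k_min <= m_loci")
  if (n_chromosomes == 1) return(if (m_loci >= k_min) 1 else 0)
  ## ways[j + 1] = number of ordered assignments of j labelled loci to the
  ## chromosomes processed so far with every per-chromosome count < k_min
  ways <- c(1, numeric(m_loci))
  for (i in seq_len(n_chromosomes)) {
    new <- numeric(m_loci + 1L)
    for (j in 0:m_loci) {
      if (ways[j + 1L] == 0) next
      cmax <- min(k_min - 1L, m_loci - j)
      for (cc in 0:cmax)
        new[j + cc + 1L] <- new[j + cc + 1L] +
          ways[j + 1L] * choose(m_loci - j, cc)
    }
    ways <- new
  }
  1 - ways[m_loci + 1L] / n_chromosomes^m_loci
}
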