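## Two-point linkage analysis, LOD grouping, maximum-likelihood marker
## ordering with a flips check, and Kosambi-scaled map construction.

#' Kosambi mapping function and its inverse
#'
#' Converts a recombination fraction to additive map distance allowing for
#' interference: `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans. The
#' inverse is `r = tanh(d / 50) / 2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return distance(s) in centimorgans.
#' @examples
#' kosambi_cm(1 / 102)  # 0.98 cM
#' kosambi_cm(1 / 168)  # ~0.6 cM
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop("recombination fraction must be in [0, 0.5); r >= 0.5 is unlinked")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @param d_cm map distance(s) in centimorgans (non-negative).
#' @return `kosambi_r()`: recombination fraction(s).
#' @export
kosambi_r <- function(d_cm) {
  if (any(d_cm < 0)) stop("map distance must be non-negative")
  tanh(d_cm / 50) / 2
}

#' Two-point recombination fraction and LOD score
#'
#' For phase-known backcross genotypes (1 = carries the scored in-phase
#' allele, 0 = lacks it, `NA` = missing), recombinants are offspring whose
#' calls disagree; `r_hat = R / N` over pairwise-complete offspring. The
#' LOD score is `R log10(r) + (N - R) log10(1 - r) + N log10(2)`, evaluated
#' at `r = r_hat` (with `0 * log10(0) = 0`, so identical vectors give
#' `N log10 2`).
#'
#' @param a,b genotype vectors (0/1/NA), indexed identically.
#' @return list of class `twopoint`: `N`, `R`, `r_hat`, `lod`.
#' @examples
#' twopoint(c(1, 1, 0, 0), c(1, 1, 0, 1))
#' @export
twopoint <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  N <- sum(ok)
  if (N == 0L) stop("no offspring informative for both markers")
  R <- sum(a[ok] != b[ok])
  r <- R / N
  term <- function(k, x) if (k == 0L) 0 else k * log10(x)
  lod <- term(R, r) + term(N - R, 1 - r) + N * log10(2)
  structure(list(N = N, R = R, r_hat = r, lod = lod), class = "twopoint")
}

#' @export
print.twopoint <- function(x, ...) {
  cat(sprintf("<twopoint> R = %d / N = %d, r_hat = %.4f, LOD = %.2f\n",
              x$R, x$N, x$r_hat, x$lod))
  invisible(x)
}

#' All pairwise two-point statistics for a genotype matrix
#'
#' @param geno numeric matrix, markers in rows (rownames = marker ids),
#'   offspring in columns; entries 0/1/NA.
#' @return list of marker-by-marker matrices `R`, `N`, `r`, `lod`.
#' @export
twopoint_matrix <- function(geno) {
  m <- nrow(geno)
  ids <- rownames(geno) %||% as.character(seq_len(m))
  R <- N <- r <- lod <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      if (j < i) { R[i, j] <- R[j, i]; N[i, j] <- N[j, i]
                   r[i, j] <- r[j, i]; lod[i, j] <- lod[j, i]; next }
      tp <- twopoint(geno[i, ], geno[j, ])
      R[i, j] <- tp$R; N[i, j] <- tp$N; r[i, j] <- tp$r_hat
      lod[i, j] <- tp$lod
    }
  }
  list(R = R, N = N, r = r, lod = lod)
}

#' Form linkage groups at a LOD threshold
#'
#' Single-linkage connected components of the marker graph with an edge
#' wherever the pairwise LOD reaches the threshold.
#'
#' @param geno genotype matrix (see [twopoint_matrix()]).
#' @param lod_threshold grouping threshold (default 3.0).
#' @return list of character vectors of marker ids, largest group first.
#' @export
form_groups <- function(geno, lod_threshold = 3.0) {
  tp <- twopoint_matrix(geno)
  lod <- tp$lod
  lod[is.na(lod)] <- -Inf
  memb <- single_linkage(-lod, -lod_threshold)  # lod >= threshold joins
  ids <- rownames(lod)
  groups <- split(ids, memb)
  groups[order(-lengths(groups), vapply(groups, `[`, "", 1L))]
}

## Multipoint log-likelihood of an order: sum over adjacent intervals of the
## backcross likelihood R log(r_hat) + (N - R) log(1 - r_hat). Intervals are
## treated independently; interference enters only through the Kosambi
## distance transform at map-building time.
multipoint_loglik <- function(geno, order) {
  ll <- 0
  for (k in seq_len(length(order) - 1L)) {
    tp <- twopoint(geno[order[k], ], geno[order[k + 1L], ])
    if (tp$R > 0L) ll <- ll + tp$R * log(tp$r_hat)
    if (tp$R < tp$N) ll <- ll + (tp$N - tp$R) * log(1 - tp$r_hat)
  }
  ll
}

## Total obligate crossovers of an order (sum of adjacent recombinant
## counts); used as a tie-break.
.obligate_crossovers <- function(geno, order) {
  sum(vapply(seq_len(length(order) - 1L), function(k)
    twopoint(geno[order[k], ], geno[order[k + 1L], ])$R, numeric(1)))
}

## Fast order log-likelihood / crossover count from precomputed two-point
## matrices (used inside the ordering search).
.ll_tpm <- function(tpm, ord) {
  i <- ord[-length(ord)]; j <- ord[-1L]
  R <- tpm$R[cbind(i, j)]; N <- tpm$N[cbind(i, j)]
  r <- R / N
  sum(ifelse(R > 0, R * log(r), 0) +
        ifelse(R < N, (N - R) * log(1 - r), 0))
}

.oc_tpm <- function(tpm, ord)
  sum(tpm$R[cbind(ord[-length(ord)], ord[-1L])])

.all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.all_perms(v[-i]), function(p) c(v[i], p)))
  out
}

## canonical orientation: first id lexicographically before last id
.canon <- function(ord) if (ord[1L] <= ord[length(ord)]) ord else rev(ord)

#' Order markers within a linkage group by maximum likelihood
#'
#' For eight or fewer markers every order is evaluated exhaustively. Above
#' that, an initial order (markers sorted by estimated distance from one
#' end) is refined by local moves: window reversals and permutations
#' (window size up to `flips_window`) and single-marker relocation, until
#' the multipoint log-likelihood stops improving. Likelihood ties break
#' toward the order minimizing total obligate crossovers, then
#' lexicographically. The flips report lists all orders within
#' `flips_margin` log-likelihood units of the best under local permutations
#' of the final order.
#'
#' @param geno genotype matrix for one linkage group (markers in rows).
#' @param max_exhaustive exhaustive-search size limit (default 8).
#' @param flips_window local-permutation window (default 3).
#' @param flips_margin log-likelihood margin for the flips report
#'   (default 2).
#' @return list with `order` (marker ids), `loglik`, `resolved` (FALSE when
#'   all markers are identical and the order is arbitrary) and `flips`
#'   (data.frame: `order`, `delta_loglik`).
#' @export
order_markers <- function(geno, max_exhaustive = 8L, flips_window = 3L,
                          flips_margin = 2) {
  m <- nrow(geno)
  ids <- rownames(geno) %||% as.character(seq_len(m))
  rownames(geno) <- ids
  if (m < 2L) stop("need at least two markers to order")
  tpm <- twopoint_matrix(geno)
  resolved <- any(tpm$R[upper.tri(tpm$R)] > 0)

  score <- function(ord) .ll_tpm(tpm, ord)
  better <- function(ord, best_ord, best_ll, ll) {
    ## TRUE if ord beats best_ord
    if (ll > best_ll + 1e-9) return(TRUE)
    if (ll < best_ll - 1e-9) return(FALSE)
    oa <- .oc_tpm(tpm, ord)
    ob <- .oc_tpm(tpm, best_ord)
    if (oa != ob) return(oa < ob)
    paste(.canon(ord), collapse = "|") < paste(.canon(best_ord), collapse = "|")
  }

  if (m <= max_exhaustive) {
    perms <- .all_perms(ids)
    ## halve the search space: keep one orientation per order
    perms <- Filter(function(p) p[1L] <= p[length(p)], perms)
    best <- perms[[1L]]; best_ll <- score(best)
    for (p in perms[-1L]) {
      ll <- score(p)
      if (better(p, best, best_ll, ll)) { best <- p; best_ll <- ll }
    }
  } else {
    ## multi-start local search: seed one candidate order per anchor marker
    ## (remaining markers sorted by Kosambi distance from the anchor), then
    ## refine each by segment reversals, single-marker relocation and
    ## window permutations until the log-likelihood stops improving
    r_capped <- pmin(tpm$r, 0.4999)
    diag(r_capped) <- 0
    refine <- function(ord) {
      ll <- score(ord)
      repeat {
        improved <- FALSE
        ## segment reversals (2-opt)
        for (i in seq_len(m - 1L)) {
          for (j in (i + 1L):m) {
            cand <- ord; cand[i:j] <- rev(cand[i:j])
            cll <- score(cand)
            if (better(cand, ord, ll, cll)) {
              ord <- cand; ll <- cll; improved <- TRUE
            }
          }
        }
        ## single-marker relocation
        for (i in seq_len(m)) {
          for (j in seq_len(m)) {
            if (i == j) next
            cand <- append(ord[-i], ord[i], after = j - 1L)
            cll <- score(cand)
            if (better(cand, ord, ll, cll)) {
              ord <- cand; ll <- cll; improved <- TRUE
            }
          }
        }
        ## local window permutations
        for (w in 2:min(flips_window, m)) {
          for (s in seq_len(m - w + 1L)) {
            idxs <- s:(s + w - 1L)
            for (pp in .all_perms(ord[idxs])[-1L]) {
              cand <- ord; cand[idxs] <- pp
              cll <- score(cand)
              if (better(cand, ord, ll, cll)) {
                ord <- cand; ll <- cll; improved <- TRUE
              }
            }
          }
        }
        if (!improved) return(list(order = ord, ll = ll))
      }
    }
    best <- NULL; best_ll <- -Inf
    for (anchor in ids) {
      d0 <- kosambi_cm(r_capped[anchor, ])
      d0[anchor] <- -Inf
      res <- refine(ids[order(d0)])
      if (is.null(best) || better(res$order, best, best_ll, res$ll)) {
        best <- res$order; best_ll <- res$ll
      }
    }
  }

  ## flips report: local permutations of the final order
  flips <- data.frame(order = paste(best, collapse = ","), delta_loglik = 0)
  for (w in 2:min(flips_window, m)) {
    for (s in seq_len(m - w + 1L)) {
      idxs <- s:(s + w - 1L)
      for (pp in .all_perms(best[idxs])[-1L]) {
        cand <- best; cand[idxs] <- pp
        dll <- score(cand) - best_ll
        if (dll >= -flips_margin)
          flips <- rbind(flips, data.frame(
            order = paste(cand, collapse = ","), delta_loglik = dll))
      }
    }
  }
  flips <- flips[!duplicated(flips$order), , drop = FALSE]
  flips <- flips[order(-flips$delta_loglik), , drop = FALSE]
  rownames(flips) <- NULL

  list(order = .canon(best), loglik = best_ll, resolved = resolved,
       flips = flips)
}

#' Build a Kosambi-scaled genetic map from an ordered group
#'
#' Adjacent distances are the Kosambi transforms of the adjacent two-point
#' recombination fraction estimates; cosegregating markers sit at distance
#' zero. The total length is the sum of adjacent distances.
#'
#' @param geno genotype matrix (markers in rows).
#' @param order marker ids in map order (e.g. from [order_markers()]).
#' @return object of class `genetic_map`: data.frame with `marker`,
#'   `position_cM`, plus attributes `total_length_cM` and
#'   `adjacent` (data.frame of interval estimates).
#' @export
build_map <- function(geno, order = rownames(geno)) {
  stopifnot(all(order %in% rownames(geno)))
  m <- length(order)
  adj <- data.frame(from = order[-m], to = order[-1L], R = NA_real_,
                    N = NA_real_, r_hat = NA_real_, cM = NA_real_)
  for (k in seq_len(m - 1L)) {
    tp <- twopoint(geno[order[k], ], geno[order[k + 1L], ])
    if (tp$r_hat >= 0.5)
      stop("adjacent markers ", order[k], " and ", order[k + 1L],
           " have r_hat >= 0.5: order or grouping is inconsistent")
    adj$R[k] <- tp$R; adj$N[k] <- tp$N; adj$r_hat[k] <- tp$r_hat
    adj$cM[k] <- kosambi_cm(tp$r_hat)
  }
  map <- data.frame(marker = order, position_cM = c(0, cumsum(adj$cM)))
  attr(map, "total_length_cM") <- sum(adj$cM)
  attr(map, "adjacent") <- adj
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map> ", nrow(x), " markers, ",
      sprintf("%.2f", attr(x, "total_length_cM")), " cM\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Pool interval estimates across crosses
#'
#' For the same marker interval scored in several crosses, the pooled
#' recombination fraction is the ratio of summed recombinant counts to
#' summed informative offspring.
#'
#' @param R vector of recombinant counts.
#' @param N vector of informative offspring counts.
#' @return list with `R`, `N`, `r_hat` and `cM` (Kosambi).
#' @examples
#' pool_recombination(c(1, 0), c(102, 66))  # 1/168 ~ 0.6 cM
#' @export
pool_recombination <- function(R, N) {
  stopifnot(length(R) == length(N), all(R >= 0), all(N >= R))
  Rt <- sum(R); Nt <- sum(N)
  r <- Rt / Nt
  list(R = Rt, N = Nt, r_hat = r, cM = kosambi_cm(r))
}
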