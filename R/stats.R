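#' @importFrom stats dhyper kruskal.test pt pwilcox pnorm p.adjust phyper
NULL

#' Conservation summary across site classes
#'
#' Aggregates per-column metrics from all retained orthogroups into the
#' standard summary: number of sites and fraction fully conserved for
#' other sites (within + outside domains), other sites within domains,
#' all ligand-binding sites pooled, and each ligand type separately. A
#' multi-ligand site counts once in the pooled ligand-binding class and
#' once in each of its ligand classes, so per-ligand counts may overlap.
#'
#' @param metrics data.frame of pooled per-column metrics (e.g. rows of
#'   \code{asMetricsFrame} applied to each orthogroup's
#'   \linkS4class{SiteMetrics}) with columns \code{class},
#'   \code{ligand_types} and \code{variable}
#' @return data.frame with columns \code{class}, \code{n_sites},
#'   \code{n_conserved}, \code{percent_conserved}
#' @export
conservationTable <- function(metrics) {
  classes <- c("other_sites", "other_sites_within_domains",
               "ligand_binding", .LIGAND_TYPES)
  if (!nrow(metrics))
    return(data.frame(class = character(), n_sites = integer(),
                      n_conserved = integer(),
                      percent_conserved = numeric()))
  m <- metrics[!is.na(metrics$variable), , drop = FALSE]
  pick <- function(sel) {
    n <- sum(sel); k <- sum(!m$variable[sel])
    c(n, k)
  }
  rows <- list(
    other_sites = pick(m$class %in% c("other_within_domain",
                                      "other_outside_domain")),
    other_sites_within_domains = pick(m$class == "other_within_domain"),
    ligand_binding = pick(m$class == "ligand_binding"))
  ligSets <- strsplit(ifelse(is.na(m$ligand_types), "", m$ligand_types), ",")
  for (lt in .LIGAND_TYPES) {
    sel <- m$class == "ligand_binding" &
      vapply(ligSets, function(x) lt %in% x, logical(1))
    rows[[lt]] <- pick(sel)
  }
  out <- data.frame(class = classes,
                    n_sites = vapply(rows, `[`, numeric(1), 1),
                    n_conserved = vapply(rows, `[`, numeric(1), 2),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$percent_conserved <- ifelse(out$n_sites > 0,
                                  100 * out$n_conserved / out$n_sites, NA)
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Point-probability method: the p-value is the sum of probabilities of
#' all hypergeometric outcomes (with the observed margins) no more likely
#' than the observed table. Computed in log space via the log-gamma based
#' \code{dhyper}, so tables with counts in the millions are handled
#' exactly.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#' @return two-sided p-value
#' @examples
#' fisherExact2x2(matrix(c(5, 5, 5, 5), 2))   # 1
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) ||
      any(tab != round(tab)))
    stop("tab must be a 2x2 matrix of non-negative integers")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) {
    warning("zero margin; p = 1")
    return(1)
  }
  x <- tab[1, 1]
  support <- max(0L, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- stats::dhyper(x, m, n, k, log = TRUE)
  min(1, sum(exp(logp[logp <= obs + 1e-7])))
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null distribution (via the Wilcoxon rank-sum distribution, or
#' full enumeration of rank splits in the presence of ties) when both
#' samples have at most 20 observations; otherwise a tie-corrected normal
#' approximation with continuity correction. The site-class comparisons
#' this package performs are always far in the asymptotic regime; the
#' exact branch exists for small fixtures.
#'
#' @param x,y numeric samples
#' @return list with \code{statistic} (U for the first sample) and
#'   \code{p.value}
#' @export
mannWhitneyU <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  hasTies <- any(ties > 1)
  if (max(n1, n2) <= 20) {
    if (!hasTies) {
      lo <- stats::pwilcox(U, n1, n2)
      hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
      return(list(statistic = U, p.value = min(1, 2 * min(lo, hi))))
    }
    if (choose(n1 + n2, n1) <= 50000) {
      # enumerate all assignments of the pooled (tied) ranks to sample x
      combs <- utils::combn(n1 + n2, n1)
      U0 <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
      mu <- n1 * n2 / 2
      p <- mean(abs(U0 - mu) >= abs(U - mu) - 1e-9)
      return(list(statistic = U, p.value = p))
    }
  }
  mu <- n1 * n2 / 2
  N <- n1 + n2
  tieAdj <- sum(ties^3 - ties)
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tieAdj / (N * (N - 1))))
  if (sigma == 0) return(list(statistic = U, p.value = 1))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(statistic = U, p.value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom (delegates to \code{stats::kruskal.test}).
#'
#' @param groups list of at least two non-empty numeric vectors
#' @return list with \code{statistic} (H), \code{p.value} and \code{df}
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) == 0L)) stop("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L)    # all observations tied: no evidence
    return(list(statistic = 0, p.value = 1,
                df = length(groups) - 1L))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter))
}

#' Conover-Iman all-pairs post-hoc comparisons
#'
#' Follows a Kruskal-Wallis test: for each pair of groups the
#' Conover-Iman t statistic on pooled ranks,
#' \deqn{t = (\bar R_i - \bar R_j) / \sqrt{S^2 \frac{N-1-H}{N-k}
#'   (1/n_i + 1/n_j)},}
#' with \eqn{S^2 = (\sum r^2 - N(N+1)^2/4)/(N-1)} (tie-corrected through
#' the midranks), referred to a t distribution on \eqn{N-k} degrees of
#' freedom; two-sided p-values are Bonferroni-adjusted over the
#' \eqn{k(k-1)/2} pairs. The direction of each pair records which group
#' has the larger mean rank (i.e. is evolving faster when applied to
#' evolutionary rates).
#'
#' @param groups named list of numeric vectors (ligand types, typically)
#' @return data.frame with one row per unordered pair: \code{group_a},
#'   \code{group_b}, \code{statistic}, \code{raw_p}, \code{adj_p},
#'   \code{neglog10_adj_p}, \code{direction} (\code{"row_faster"} when
#'   \code{group_a} has the larger mean rank, else \code{"col_faster"});
#'   the Kruskal-Wallis H used is attached as attribute \code{"H"}
#' @export
conoverPosthoc <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  gidx <- rep(seq_len(k), lengths(groups))
  N <- length(pooled)
  r <- rank(pooled)
  H <- kruskalWallis(groups)$statistic
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  meanRank <- tapply(r, gidx, mean)
  n <- lengths(groups)
  pairs <- utils::combn(k, 2)
  nPairs <- ncol(pairs)
  out <- data.frame(group_a = names(groups)[pairs[1, ]],
                    group_b = names(groups)[pairs[2, ]],
                    statistic = NA_real_, raw_p = NA_real_,
                    adj_p = NA_real_, neglog10_adj_p = NA_real_,
                    direction = NA_character_,
                    stringsAsFactors = FALSE)
  scale2 <- S2 * (N - 1 - H) / (N - k)
  for (q in seq_len(nPairs)) {
    i <- pairs[1, q]; j <- pairs[2, q]
    if (n[i] < 2L || n[j] < 2L) next     # pair not testable
    num <- meanRank[[i]] - meanRank[[j]]
    den <- sqrt(scale2 * (1 / n[i] + 1 / n[j]))
    # degenerate spreads: no rank variance left (all values tied, or
    # perfect group separation with H = N - 1)
    tstat <- if (den > 0) num / den else if (num == 0) 0 else Inf * sign(num)
    p <- 2 * stats::pt(-abs(tstat), df = N - k)
    out$statistic[q] <- tstat
    out$raw_p[q] <- min(1, p)
    out$direction[q] <- if (meanRank[[i]] > meanRank[[j]])
      "row_faster" else "col_faster"
  }
  out$adj_p <- pmin(1, out$raw_p * nPairs)
  out$neglog10_adj_p <- -log10(out$adj_p)
  attr(out, "H") <- H
  out
}

#' Fisher test of conservation between two site classes
#'
#' Builds the conserved-versus-variable 2x2 table for two rows of a
#' conservation summary and applies \code{\link{fisherExact2x2}}.
#'
#' @param summary data.frame from \code{\link{conservationTable}}, or any
#'   table with \code{class}, \code{n_sites} and either
#'   \code{n_conserved} or \code{percent_conserved}
#' @param classA,classB class labels to compare
#' @return two-sided p-value
#' @export
conservationFisher <- function(summary, classA, classB) {
  row <- function(cl) {
    r <- summary[summary$class == cl, , drop = FALSE]
    if (nrow(r) != 1L) stop("class not found in summary: ", cl)
    n <- r$n_sites
    k <- if ("n_conserved" %in% names(r) && !is.na(r$n_conserved))
      r$n_conserved else round(n * r$percent_conserved / 100)
    c(conserved = k, variable = n - k)
  }
  fisherExact2x2(rbind(row(classA), row(classB)))
}
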