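#' Map a gene list onto the background universe
#'
#' Overrepresentation statistics are only defined for list genes that the
#' annotation background knows about; unmapped symbols are dropped (and
#' reported), mirroring the shrinkage from submitted symbols to recognized
#' identifiers seen with annotation services.
#'
#' @param gene_list character vector of gene symbols (uppercased
#'   internally).
#' @param background character vector: the background universe of symbols.
#' @return character vector of mappable (intersected) symbols, with the
#'   unmapped symbols attached as attribute `"unmapped"`.
#' @examples
#' mapToUniverse(c("INVS", "DNAH1", "NOT_A_GENE"), c("INVS", "DNAH1", "TTN"))
#' @export
mapToUniverse <- function(gene_list, background) {
  if (!length(background)) stop("background universe is empty")
  gene_list <- unique(toupper(gene_list))
  background <- unique(toupper(background))
  mappable <- intersect(gene_list, background)
  if (!length(mappable)) {
    stop("no gene of the list maps to the background universe; no statistic computable")
  }
  attr(mappable, "unmapped") <- setdiff(gene_list, background)
  mappable
}

#' Hypergeometric right-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of observing
#' k or more annotated genes in a list of n drawn from a universe of N
#' containing K annotated genes.  The sum runs over i = k .. min(n, K) with
#' each term evaluated in log space (`lchoose`) and combined by
#' log-sum-exp, so small tail probabilities are computed stably.  This is
#' the one-sided Fisher exact test of the standard 2x2 enrichment table.
#'
#' @param k observed annotated genes in the list (vectorized).
#' @param n list size.
#' @param K annotated genes in the background.
#' @param N background size.
#' @return Tail probability in `[0, 1]`, vectorized over the inputs.
#' @examples
#' hypergeomRightTail(2, 5, 4, 20)   # 0.24871...
#' hypergeomRightTail(0, 5, 4, 20)   # right tail from zero is 1
#' @export
hypergeomRightTail <- function(k, n, K, N) {
  args <- cbind(k, n, K, N)
  apply(args, 1, function(a) {
    k <- a[1]; n <- a[2]; K <- a[3]; N <- a[4]
    if (any(c(k, n, K, N) < 0) || n > N || K > N) {
      stop("hypergeomRightTail: require 0 <= n, K <= N")
    }
    if (k > K || k > n) {
      stop(sprintf("hypergeomRightTail: impossible configuration k=%g > min(n=%g, K=%g)",
                   k, n, K))
    }
    if (k <= 0) return(1)
    i <- k:min(n, K)
    logTerms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    min(1, exp(.logSumExp(logTerms)))
  })
}

#' EASE score (conservative enrichment p-value)
#'
#' The jackknifed variant of the one-sided Fisher test: one annotated gene
#' is removed from the gene list before testing, i.e. the right tail is
#' taken at (k - 1) hits in a list of (n - 1) against the unchanged
#' background.  This penalizes terms supported by very few list genes --
#' a single-hit term scores exactly 1 -- and is everywhere at least as
#' large as [hypergeomRightTail()].
#'
#' @inheritParams hypergeomRightTail
#' @return Tail probability in `[0, 1]`, vectorized over the inputs.
#' @examples
#' easeScore(1, 5, 4, 20)   # 1: a singleton hit carries no evidence
#' easeScore(2, 5, 4, 20) >= hypergeomRightTail(2, 5, 4, 20)
#' @export
easeScore <- function(k, n, K, N) {
  args <- cbind(k, n, K, N)
  apply(args, 1, function(a) {
    k <- a[1]; n <- a[2]; K <- a[3]; N <- a[4]
    if (k <= 0) return(1)
    hypergeomRightTail(k - 1, n - 1, K, N)
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BH"` (default), `"bonferroni"`, or `"none"`.
#' @return Adjusted p-values, all at most 1.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))   # all 0.03
#' @export
bhAdjust <- function(p_values, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = method)
}

#' Gene-set overrepresentation analysis
#'
#' Tests each term for overrepresentation of its member genes in the
#' mappable gene list against a background universe.  For a term with K
#' background members, k of which are in the mappable list of size n drawn
#' from a universe of N, the raw p-value is the EASE score (default) or
#' the plain hypergeometric right tail; reported alongside are the
#' percentage column `pct = 100 k / n` (half-up, two decimals), the fold
#' enrichment `(k/n) / (K/N)`, the adjusted p-value, and the member genes.
#'
#' The default background is the annotation universe: every gene covered
#' by the supplied term sets.  Terms with fewer than `min_count` list hits
#' are suppressed.
#'
#' @param gene_list character vector of gene symbols (e.g. all genes with
#'   retained variants across families, duplicates removed).
#' @param termSets a [TermSets-class] collection.
#' @param background background universe; defaults to
#'   `universeGenes(termSets)`.
#' @param ease use the conservative EASE score (default TRUE); FALSE gives
#'   the plain one-sided Fisher/hypergeometric tail.
#' @param min_count minimum list hits for a term to be reported
#'   (default 2).
#' @param adjust multiplicity adjustment: `"BH"` (default),
#'   `"bonferroni"`, `"none"`.
#' @return data.frame sorted by ascending `p_raw` with columns `term_id`,
#'   `term_name`, `count`, `n_list`, `K_background`, `N_background`,
#'   `pct`, `fold_enrichment`, `p_raw`, `p_adjusted`, `genes`
#'   (comma-joined hits).
#' @examples
#' ts <- TermSets(c("T1", "T2"), c("first", "second"),
#'                list(c("A", "B", "C"), c("C", "D", "E", "F")))
#' enrich(c("A", "B", "C", "D"), ts, min_count = 1)
#' @export
enrich <- function(gene_list, termSets, background = universeGenes(termSets),
                   ease = TRUE, min_count = 2L,
                   adjust = c("BH", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  background <- unique(toupper(background))
  mappable <- mapToUniverse(gene_list, background)
  n <- length(mappable)
  N <- length(background)
  tg <- termGenes(termSets)
  rows <- lapply(seq_along(tg), function(i) {
    memb <- intersect(tg[[i]], background)
    K <- length(memb)
    hits <- intersect(memb, mappable)
    k <- length(hits)
    if (k < min_count || K == 0) return(NULL)
    p <- if (ease) easeScore(k, n, K, N) else hypergeomRightTail(k, n, K, N)
    data.frame(term_id = termIds(termSets)[i],
               term_name = termNames(termSets)[i],
               count = k, n_list = n, K_background = K, N_background = N,
               pct = roundHalfUp(100 * k / n, 2),
               fold_enrichment = (k / n) / (K / N),
               p_raw = p,
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      count = integer(0), n_list = integer(0),
                      K_background = integer(0), N_background = integer(0),
                      pct = numeric(0), fold_enrichment = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      genes = character(0))
    return(out)
  }
  out$p_adjusted <- bhAdjust(out$p_raw, method = adjust)
  out <- out[order(out$p_raw, -out$count, out$term_id), , drop = FALSE]
  out <- out[, c("term_id", "term_name", "count", "n_list", "K_background",
                 "N_background", "pct", "fold_enrichment", "p_raw",
                 "p_adjusted", "genes")]
  rownames(out) <- NULL
  out
}
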