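#' Fold enrichment of a gene set within a hit group
#'
#' The ratio of a set's frequency in the hit group to its frequency in the
#' measured background universe: `(k/n) / (K/N)`. With the screen's numbers,
#' 104 of 230 Low-tail strains falling in a 293-gene set over a 4609-gene
#' universe gives 7.1-fold.
#'
#' @param k overlap count (hits in the set).
#' @param n hit-group size.
#' @param K background count (set members in the universe).
#' @param N universe size (genes with a measured score).
#' @return fold enrichment (numeric).
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(K == 0)) stop("fold enrichment undefined for K = 0")
  check_hyper_args(k, n, K, N)
  (k / n) / (K / N)
}

check_hyper_args <- function(k, n, K, N) {
  stopifnot(is.numeric(k), is.numeric(n), is.numeric(K), is.numeric(N))
  if (any(n <= 0) || any(N <= 0) || any(K < 0) || any(k < 0)) {
    stop("hypergeometric parameters must satisfy n > 0, N > 0, K >= 0, k >= 0")
  }
  if (any(K > N) || any(n > N) || any(k > pmin(n, K))) {
    stop("inconsistent hypergeometric parameters: need K <= N, n <= N, ",
         "k <= min(n, K)")
  }
  invisible(TRUE)
}

# log of the hypergeometric pmf at i, vectorized over i
hyper_lpmf <- function(i, n, K, N) {
  lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

#' Exact hypergeometric tail probability
#'
#' Probability of the observed overlap between a hit group and a labelled
#' gene set when drawing without replacement from a finite universe:
#' `upper` gives P(X >= k) (over-representation), `lower` gives P(X <= k)
#' (depletion), for X ~ Hypergeometric(N, K, n). Computed by exact
#' summation of the pmf in log space, so extreme tails do not underflow.
#'
#' @inheritParams fold_enrichment
#' @param tail "upper" or "lower".
#' @return tail probability in [0, 1].
#' @export
hypergeom_tail <- function(k, n, K, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  check_hyper_args(k, n, K, N)
  supp_lo <- max(0, n - (N - K))
  supp_hi <- min(n, K)
  if (tail == "upper") {
    if (k <= supp_lo) return(1)
    if (k > supp_hi) return(0)
    i <- seq(k, supp_hi)
  } else {
    if (k < supp_lo) return(0)
    if (k >= supp_hi) return(1)
    i <- seq(supp_lo, k)
  }
  p <- exp(logsumexp(hyper_lpmf(i, n, K, N)))
  min(max(p, 0), 1)
}

#' Gene-set collection over a measured universe
#'
#' Restricts each set to the universe of genes that received a score in the
#' screen (the enrichment background); empty sets after intersection are
#' dropped.
#'
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of measured gene identifiers.
#' @return list with class `gene_set_collection`: `universe`, `sets`,
#'   `descriptions`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)), is.character(universe))
  universe <- unique(universe)
  desc <- attr(sets, "description")
  trimmed <- lapply(sets, function(s) intersect(unique(s), universe))
  keep <- vapply(trimmed, length, integer(1)) >= 1L
  structure(list(universe = universe, sets = trimmed[keep],
                 descriptions = if (is.null(desc)) {
                   stats::setNames(rep("", sum(keep)), names(trimmed)[keep])
                 } else {
                   desc[names(trimmed)[keep]]
                 }),
            class = "gene_set_collection")
}

#' Term enrichment of a hit group
#'
#' Tests every term of a collection for over-representation in a hit group
#' with the exact upper-tail hypergeometric test against the measured
#' background, reporting overlap ("Hits"), background count ("Bkg"), fold
#' enrichment and raw p-value. Terms with `p < p_cutoff` and
#' `fold > fold_min` are flagged significant. Rows are ordered by
#' descending fold.
#'
#' @param group character vector of hit strains; members outside the
#'   universe are dropped with a warning.
#' @param collection a [gene_set_collection()].
#' @param p_cutoff raw p-value cutoff for the significance flag.
#' @param fold_min minimum fold enrichment for the significance flag.
#' @param adjust "none" (raw p, the default) or "BH" for
#'   Benjamini-Hochberg-adjusted p in an extra `p_adj` column (the flag then
#'   uses `p_adj`).
#' @return data.frame of EnrichmentRows: term, description, k, n, K, N,
#'   fold, p, (p_adj,) significant, hit_genes (comma-joined).
#' @export
enrich_terms <- function(group, collection, p_cutoff = 0.01, fold_min = 2.0,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(group) == 0L) stop("empty hit group")
  group <- unique(group)
  outside <- setdiff(group, collection$universe)
  if (length(outside)) {
    warning(length(outside), " group member(s) outside the universe dropped")
    group <- setdiff(group, outside)
  }
  n <- length(group)
  N <- length(collection$universe)
  rows <- lapply(names(collection$sets), function(id) {
    members <- collection$sets[[id]]
    hit <- intersect(group, members)
    k <- length(hit)
    if (k == 0L) return(NULL)
    K <- length(members)
    data.frame(term = id,
               description = unname(collection$descriptions[id]),
               k = k, n = n, K = K, N = N,
               fold = fold_enrichment(k, n, K, N),
               p = hypergeom_tail(k, n, K, N, "upper"),
               hit_genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), description = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p = numeric(),
                      hit_genes = character(), stringsAsFactors = FALSE)
  }
  p_for_flag <- out$p
  if (adjust == "BH" && nrow(out)) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    p_for_flag <- out$p_adj
  }
  out$significant <- p_for_flag < p_cutoff & out$fold > fold_min
  out <- out[order(-out$fold, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trim redundant enriched terms
#'
#' A simplified overlap-based surrogate for ontology-aware redundancy
#' trimming: among significant terms whose hit-gene sets have Jaccard
#' similarity at or above the threshold, only the best-supported term
#' (smallest p, ties by larger fold then lexical term id) survives. It uses
#' no ontology structure, only the observed hit sets; outputs are tagged
#' accordingly.
#'
#' @param rows EnrichmentRow data.frame from [enrich_terms()] (rows must
#'   carry `hit_genes`).
#' @param jaccard_threshold similarity at or above which two terms are
#'   considered redundant.
#' @return the surviving rows, same columns, with attribute
#'   `trim_method = "jaccard_surrogate"`.
#' @export
trim_redundant <- function(rows, jaccard_threshold = 0.8) {
  sig <- which(rows$significant)
  if (length(sig) <= 1L) {
    attr(rows, "trim_method") <- "jaccard_surrogate"
    return(rows)
  }
  hits <- strsplit(rows$hit_genes[sig], ",", fixed = TRUE)
  ord <- order(rows$p[sig], -rows$fold[sig], rows$term[sig])
  keep <- logical(length(sig))
  for (j in ord) {
    redundant <- FALSE
    for (j2 in which(keep)) {
      a <- hits[[j]]; b <- hits[[j2]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      if (jac >= jaccard_threshold) { redundant <- TRUE; break }
    }
    if (!redundant) keep[j] <- TRUE
  }
  drop_idx <- sig[!keep]
  out <- if (length(drop_idx)) rows[-drop_idx, , drop = FALSE] else rows
  rownames(out) <- NULL
  attr(out, "trim_method") <- "jaccard_surrogate"
  out
}

#' Direction-aware overlap test between a hit group and one gene set
#'
#' Intersects the set with the measured universe first (a 341-strain
#' respiration-deficient list reduces to the 293 measured members), then
#' reports the overlap, its fold enrichment, the deviation direction
#' (enriched if k exceeds the chance expectation n*K/N, depleted otherwise;
#' exact equality counts as enriched), and the exact tail p-value in the
#' direction of deviation.
#'
#' @param group character vector of hit strains.
#' @param gene_set character vector, the labelled set.
#' @param universe character vector of measured genes.
#' @return list: k, n, K, N, fold, p, direction ("enriched" | "depleted").
#' @export
set_overlap_test <- function(group, gene_set, universe) {
  universe <- unique(universe)
  gene_set <- intersect(unique(gene_set), universe)
  if (length(gene_set) == 0L) stop("gene set has no members in the universe")
  group <- intersect(unique(group), universe)
  k <- length(intersect(group, gene_set))
  n <- length(group)
  K <- length(gene_set)
  N <- length(universe)
  expected <- n * K / N
  direction <- if (k >= expected) "enriched" else "depleted"
  p <- hypergeom_tail(k, n, K, N,
                      tail = if (direction == "enriched") "upper" else "lower")
  list(k = k, n = n, K = K, N = N,
       fold = fold_enrichment(k, n, K, N), p = p, direction = direction)
}
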