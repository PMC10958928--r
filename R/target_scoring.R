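#' Binomial upper-tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p), evaluated through the survival
#' function (`stats::pbinom` upper tail) for numerical stability; exactly
#' 1 for `k = 0`. This is the core quantity of formula-target
#' identification: the chance that a target is hit by `k` or more of the
#' `n` active formula compounds under the background hit probability `p`.
#'
#' @param k observed hit count, `0 <= k <= n`. Vectorized.
#' @param n number of active compounds (trials).
#' @param p background hit probability in `[0, 1]`.
#' @return numeric vector of tail probabilities.
#' @examples
#' binomial_tail(1, 2, 0.5)  # 0.75
#' @export
binomial_tail <- function(k, n, p) {
  if (any(k < 0) || any(k > n)) nf_stop("need 0 <= k <= n")
  if (any(p < 0) || any(p > 1)) nf_stop("p must lie in [0, 1]")
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

# Score-filtered view of a compound-target table: links at or above the
# threshold survive; the 9999 sentinel (curated, score-less) always does.
filter_links <- function(ct_links, score_threshold) {
  ct_links[ct_links$score >= score_threshold | ct_links$score == 9999, ,
           drop = FALSE]
}

#' Background hit probabilities per target
#'
#' From a score-filtered compound-target table, estimates for each target
#' the probability that a randomly chosen compound of the table links to
#' it: the number of distinct compounds hitting the target divided by the
#' number of distinct compounds in the filtered table. Targets with no
#' surviving link are absent from the result.
#'
#' @param ct_links scored links from [read_links()].
#' @param score_threshold minimum association score; 9999 always passes.
#' @return named numeric vector, `target -> p`.
#' @export
background_probs <- function(ct_links, score_threshold = 400) {
  keep <- filter_links(ct_links, score_threshold)
  if (!nrow(keep))
    nf_stop("no compound-target link survives score threshold %d",
            as.integer(score_threshold))
  n_compounds <- length(unique(keep$compound_id))
  hits <- tapply(keep$compound_id, keep$target,
                 function(x) length(unique(x)))
  p <- as.numeric(hits) / n_compounds
  names(p) <- names(hits)
  p
}

# Rank significant targets ascending by p-value (ties: larger k first,
# then target id) and apply the piecewise gene score:
# -log(pval) / rank below psig, 0 otherwise.
rank_gene_scores <- function(target, k, pval, psig, log_base,
                             degenerate = rep(FALSE, length(pval))) {
  ord <- order(pval, -k, target)
  target <- target[ord]; k <- k[ord]; pval <- pval[ord]
  degenerate <- degenerate[ord]
  sig <- pval < psig
  rank <- rep(NA_integer_, length(pval))
  rank[sig] <- seq_len(sum(sig))
  gene_score <- numeric(length(pval))
  gene_score[sig] <- -log(pval[sig], base = log_base) / rank[sig]
  data.frame(target = target, k = k, pval = pval, rank = rank,
             gene_score = gene_score, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Profile the targets of a formula
#'
#' The binomial formula-target identification model. For each target hit
#' by at least one active compound (after score filtering), the observed
#' hit count `k` out of `n = |active compounds|` trials is compared with
#' its background probability via [binomial_tail()]. Significant targets
#' (`pval < psig`) are ranked ascending by p-value and scored
#' `gene_score = -log(pval) / rank`; non-significant targets score 0.
#' Each active compound then receives a `chem_score`: the arithmetic mean
#' of the gene scores of the profiled targets it hits (zeros included), or
#' 0 if it hits none.
#'
#' A target with background probability 0 but `k >= 1` is impossible under
#' the null; it is reported with the smallest positive normal double as
#' p-value and flagged in the `degenerate` column.
#'
#' @param active_compounds character vector of active compound ids (e.g.
#'   the drug-likeness pass-set).
#' @param ct_links scored compound-target links.
#' @param background named probability vector from [background_probs()];
#'   computed from `ct_links` at `config$score_threshold` when `NULL`. It
#'   must cover every target reachable from the active compounds.
#' @param config an [nf_config()]; uses `score_threshold`, `psig`,
#'   `log_base`.
#' @return a `formula_profile`: list with `targets` (data.frame `target`,
#'   `k`, `n`, `p`, `pval`, `rank`, `gene_score`, `degenerate`),
#'   `chem_scores` (named numeric over the active compounds), `n_active`
#'   and the config snapshot.
#' @export
profile_formula <- function(active_compounds, ct_links, background = NULL,
                            config = nf_config()) {
  active_compounds <- unique(as.character(active_compounds))
  if (!length(active_compounds)) nf_stop("'active_compounds' must be non-empty")
  if (is.null(background))
    background <- background_probs(ct_links, config$score_threshold)
  keep <- filter_links(ct_links, config$score_threshold)
  hits <- unique(keep[keep$compound_id %in% active_compounds,
                      c("compound_id", "target")])
  if (!nrow(hits))
    nf_stop("no active compound hits any target at score threshold %d",
            config$score_threshold)
  n <- length(active_compounds)
  k <- table(hits$target)
  targets <- names(k)
  missing_bg <- setdiff(targets, names(background))
  if (length(missing_bg))
    nf_stop("target(s) missing from the background: %s",
            paste(missing_bg, collapse = ", "))
  p <- unname(background[targets])
  k <- as.integer(k)
  degenerate <- p == 0 & k >= 1
  pval <- binomial_tail(k, n, p)
  pval[degenerate] <- .Machine$double.xmin
  tab <- rank_gene_scores(targets, k, pval, config$psig, config$log_base,
                          degenerate)
  tab$n <- n
  tab$p <- p[match(tab$target, targets)]
  tab <- tab[c("target", "k", "n", "p", "pval", "rank", "gene_score",
               "degenerate")]
  score_of <- setNames(tab$gene_score, tab$target)
  chem_scores <- vapply(active_compounds, function(cid) {
    tg <- hits$target[hits$compound_id == cid]
    if (!length(tg)) 0 else mean(score_of[tg])
  }, numeric(1))
  structure(list(targets = tab, chem_scores = chem_scores, n_active = n,
                 config = config[c("score_threshold", "psig", "log_base")]),
            class = "formula_profile")
}

#' @export
print.formula_profile <- function(x, ...) {
  n_sig <- sum(!is.na(x$targets$rank))
  cat(sprintf("<formula_profile> %d targets (%d significant at psig = %g), %d active compounds\n",
              nrow(x$targets), n_sig, x$config$psig, x$n_active))
  invisible(x)
}

#' Core targets of a formula profile
#'
#' Targets with a positive gene score, ordered by score descending (ties:
#' p-value ascending, then target id).
#'
#' @param profile a `formula_profile` from [profile_formula()].
#' @return data.frame with columns `target`, `gene_score`, `pval`, `rank`;
#'   zero rows when nothing is significant.
#' @export
core_targets <- function(profile) {
  tab <- profile$targets
  tab <- tab[tab$gene_score > 0, , drop = FALSE]
  tab <- tab[order(-tab$gene_score, tab$pval, tab$target), , drop = FALSE]
  rownames(tab) <- NULL
  tab[c("target", "gene_score", "pval", "rank")]
}
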