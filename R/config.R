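#' Analysis configuration
#'
#' Bundles every tunable parameter of the toolkit with its default, so that
#' one object can be threaded through screening, target profiling,
#' proximity testing and prescription mining. Defaults follow the
#' platform's conventional settings: a STITCH-style medium-confidence
#' association cutoff of 400 (on the 0--1000 scale, with 9999 the sentinel
#' for curated score-less links), significance level `psig = 0.05` on the
#' binomial tail, KATZ path coefficient `beta = 0.001` over walks of length
#' up to 3, and core-formula mining at confidence level `alpha = 0.9` with
#' a minimum support `s_min = 0.1`.
#'
#' @param qed_min minimum QED value a compound must reach to pass
#'   drug-likeness screening (0--1).
#' @param lipinski_max_violations maximum tolerated Lipinski rule-of-five
#'   violations (0--4); the conventional reading allows one.
#' @param veber_max_violations maximum tolerated Veber rule violations
#'   (0--2).
#' @param score_threshold minimum compound--target association score
#'   (0--1000); the sentinel 9999 always passes.
#' @param psig significance threshold on the binomial tail probability
#'   P(X >= k) for calling a core target.
#' @param log_base base of the logarithm in the gene score numerator:
#'   `10` or `"e"`.
#' @param top_n depth of the shared-term co-association curve.
#' @param beta KATZ path score coefficient; walks of length l contribute
#'   with weight `beta^l`.
#' @param max_path_len maximum walk length counted by the KATZ score.
#' @param n_perm number of permutations for the empirical nulls.
#' @param seed integer seed driving every source of randomness.
#' @param s_min minimum support S_alpha for a mined core formula; typical
#'   values lie between 0.01 and 0.3.
#' @param alpha confidence level defining support: a prescription supports
#'   a formula when it contains at least a fraction `alpha` of its herbs.
#' @param min_herbs minimum number of herbs in a core formula (>= 2).
#' @param desired_herbs desired core-formula size, or `NULL`.
#' @param enforce_size keep only cliques whose size equals
#'   `desired_herbs`.
#' @param fallback when `enforce_size` finds nothing, fall back to plain
#'   `min_herbs` filtering instead of returning an empty result.
#' @param merge merge highly similar core formulas after mining.
#' @param merge_method `"Together"` (merge similarity components
#'   collectively) or `"Step"` (merge the most similar pair repeatedly).
#' @param merge_threshold Jaccard similarity at or above which formulas are
#'   merged; values above 0.6 are recommended.
#' @param person_stats also compute patient-based support.
#'
#' @return an object of class `nf_config`: a validated named list.
#' @examples
#' cfg <- nf_config(psig = 0.01, n_perm = 200)
#' cfg$psig
#' @export
nf_config <- function(qed_min = 0.3,
                      lipinski_max_violations = 1L,
                      veber_max_violations = 1L,
                      score_threshold = 400L,
                      psig = 0.05,
                      log_base = 10,
                      top_n = 30L,
                      beta = 0.001,
                      max_path_len = 3L,
                      n_perm = 1000L,
                      seed = 0L,
                      s_min = 0.1,
                      alpha = 0.9,
                      min_herbs = 3L,
                      desired_herbs = NULL,
                      enforce_size = FALSE,
                      fallback = FALSE,
                      merge = FALSE,
                      merge_method = c("Together", "Step"),
                      merge_threshold = 0.6,
                      person_stats = FALSE) {
  if (identical(log_base, "e")) log_base <- exp(1)
  if (!is.numeric(log_base) || !(isTRUE(all.equal(log_base, 10)) ||
                                 isTRUE(all.equal(log_base, exp(1)))))
    nf_stop("log_base must be 10 or \"e\"")
  merge_method <- match.arg(merge_method)
  cfg <- list(
    qed_min = as.numeric(qed_min),
    lipinski_max_violations = as.integer(lipinski_max_violations),
    veber_max_violations = as.integer(veber_max_violations),
    score_threshold = as.integer(score_threshold),
    psig = as.numeric(psig),
    log_base = as.numeric(log_base),
    top_n = as.integer(top_n),
    beta = as.numeric(beta),
    max_path_len = as.integer(max_path_len),
    n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    s_min = as.numeric(s_min),
    alpha = as.numeric(alpha),
    min_herbs = as.integer(min_herbs),
    desired_herbs = if (!is.null(desired_herbs)) as.integer(desired_herbs),
    enforce_size = isTRUE(enforce_size),
    fallback = isTRUE(fallback),
    merge = isTRUE(merge),
    merge_method = merge_method,
    merge_threshold = as.numeric(merge_threshold),
    person_stats = isTRUE(person_stats)
  )
  validate_config(cfg)
  structure(cfg, class = "nf_config")
}

validate_config <- function(cfg) {
  if (!(cfg$psig > 0 && cfg$psig < 1)) nf_stop("psig must lie in (0, 1)")
  if (!(cfg$s_min >= 0 && cfg$s_min <= 1)) nf_stop("s_min must lie in [0, 1]")
  if (!(cfg$alpha > 0 && cfg$alpha <= 1)) nf_stop("alpha must lie in (0, 1]")
  if (!(cfg$merge_threshold >= 0 && cfg$merge_threshold <= 1))
    nf_stop("merge_threshold must lie in [0, 1]")
  if (cfg$n_perm < 1L) nf_stop("n_perm must be >= 1")
  if (cfg$min_herbs < 2L) nf_stop("min_herbs must be >= 2")
  if (cfg$qed_min < 0 || cfg$qed_min > 1) nf_stop("qed_min must lie in [0, 1]")
  if (cfg$beta <= 0) nf_stop("beta must be positive")
  if (cfg$max_path_len < 1L) nf_stop("max_path_len must be >= 1")
  invisible(cfg)
}

#' @export
print.nf_config <- function(x, ...) {
  cat("<nf_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

# Merge a plain named list (e.g. from a YAML config file) over the defaults;
# unknown names are an error so typos in config files surface immediately.
config_from_list <- function(values) {
  values <- values %||% list()
  known <- names(formals(nf_config))
  bad <- setdiff(names(values), known)
  if (length(bad))
    nf_stop("unknown configuration field(s): %s", paste(bad, collapse = ", "))
  do.call(nf_config, values)
}
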