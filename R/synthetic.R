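#' Synthetic fixture specification
#'
#' One object describing the study conditions emulated by every generator:
#' problem sizes, planted signal and noise levels. Defaults mirror the
#' package's reference simulation settings: 500 prescriptions over 250
#' patients with a 5-herb core formula present intact in 60% of them; a
#' 500-compound chemical background at link density 0.02 in which the 50
#' formula compounds hit one planted target at tenfold density; gene-set
#' collections of 50 terms over 2000 genes. All generators are pure
#' functions of this spec: identical seeds give identical outputs
#' (R's Mersenne-Twister RNG).
#'
#' @param seed integer seed.
#' @param n_herbs number of noise herbs (planted herbs are extra).
#' @param n_compounds total compounds in the chemical background.
#' @param n_formula_compounds number of active formula compounds (a subset
#'   of the background).
#' @param n_targets number of protein targets.
#' @param n_genes size of the gene universe for gene sets.
#' @param n_terms number of gene-set terms.
#' @param n_patients,n_prescriptions cohort sizes; prescriptions are dealt
#'   to patients round-robin, so patients can have several visits.
#' @param planted_formula character vector of planted herbs, or `NULL` for
#'   the default `PF1..PF5`.
#' @param presence_rate probability that a prescription contains the
#'   planted formula intact.
#' @param enrichment_factor link-density multiplier of the planted target
#'   (or planted term) over background; 1 means no planted signal.
#' @param link_density background compound-target link probability.
#' @param herbs_min,herbs_max range of herbs per prescription.
#' @param term_size_min,term_size_max range of genes per term.
#' @param query_size size of the emitted query gene set.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 0L,
                         n_herbs = 30L,
                         n_compounds = 500L,
                         n_formula_compounds = 50L,
                         n_targets = 200L,
                         n_genes = 2000L,
                         n_terms = 50L,
                         n_patients = 250L,
                         n_prescriptions = 500L,
                         planted_formula = NULL,
                         presence_rate = 0.6,
                         enrichment_factor = 10,
                         link_density = 0.02,
                         herbs_min = 8L,
                         herbs_max = 15L,
                         term_size_min = 10L,
                         term_size_max = 50L,
                         query_size = 50L) {
  spec <- list(seed = as.integer(seed), n_herbs = as.integer(n_herbs),
               n_compounds = as.integer(n_compounds),
               n_formula_compounds = as.integer(n_formula_compounds),
               n_targets = as.integer(n_targets),
               n_genes = as.integer(n_genes), n_terms = as.integer(n_terms),
               n_patients = as.integer(n_patients),
               n_prescriptions = as.integer(n_prescriptions),
               planted_formula = planted_formula %||% paste0("PF", 1:5),
               presence_rate = as.numeric(presence_rate),
               enrichment_factor = as.numeric(enrichment_factor),
               link_density = as.numeric(link_density),
               herbs_min = as.integer(herbs_min),
               herbs_max = as.integer(herbs_max),
               term_size_min = as.integer(term_size_min),
               term_size_max = as.integer(term_size_max),
               query_size = as.integer(query_size))
  counts <- c("n_herbs", "n_compounds", "n_formula_compounds", "n_targets",
              "n_genes", "n_terms", "n_patients", "n_prescriptions")
  if (any(unlist(spec[counts]) < 1L)) nf_stop("all counts must be >= 1")
  if (!(spec$presence_rate > 0 && spec$presence_rate <= 1))
    nf_stop("presence_rate must lie in (0, 1]")
  if (!(spec$link_density > 0 && spec$link_density < 1))
    nf_stop("link_density must lie in (0, 1)")
  if (spec$enrichment_factor < 1) nf_stop("enrichment_factor must be >= 1")
  if (spec$enrichment_factor * spec$link_density > 1)
    nf_stop("enrichment_factor x link_density must not exceed 1")
  if (spec$n_formula_compounds > spec$n_compounds)
    nf_stop("n_formula_compounds must not exceed n_compounds")
  if (spec$herbs_min > spec$herbs_max || spec$herbs_min < 1L)
    nf_stop("invalid herbs-per-prescription range")
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic interaction network
#'
#' A connected preferential-attachment (Barabasi-Albert) graph standing in
#' for a protein-protein interaction network; simple, undirected,
#' deterministic under the seed. Vertex names are `G1..Gn`.
#'
#' @param n_nodes number of nodes.
#' @param edges_per_node edges attached by each incoming node
#'   (`< n_nodes`).
#' @param seed integer seed.
#' @return an igraph.
#' @export
gen_ppi <- function(n_nodes, edges_per_node = 2L, seed = 0L) {
  if (!(n_nodes > edges_per_node && edges_per_node >= 1L))
    nf_stop("need n_nodes > edges_per_node >= 1")
  g <- with_seed(seed,
                 igraph::sample_pa(n_nodes, m = edges_per_node,
                                   directed = FALSE))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- paste0("G", seq_len(n_nodes))
  g
}

#' Generate a synthetic compound-target table with a planted target
#'
#' Compounds `C1..Cn` receive descriptors drawn from ranges straddling the
#' drug-likeness boundaries. Background compound-target links appear with
#' probability `link_density`, scored uniformly on 150..999. The first
#' `n_formula_compounds` compounds form the active formula; the planted
#' target `TPLANT` links to them with probability
#' `enrichment_factor x link_density` (scores >= 400), while behaving like
#' background everywhere else. At factor 1 the planted target is generated
#' exactly like background, giving a null calibration fixture.
#'
#' @param spec a [fixture_spec()].
#' @return list with `compounds` (descriptor table), `links` (scored
#'   links), `hc_links` (herb-compound links: formula compounds dealt over
#'   the herbs `HerbA`--`HerbC`, the rest over a background herb pool),
#'   `formula_compounds` (character vector) and `planted_target`.
#' @export
gen_compound_target <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$link_density * spec$n_compounds < 1)
    nf_stop("link_density x n_compounds must be >= 1")
  with_seed(spec$seed, {
    nC <- spec$n_compounds
    ids <- sprintf("C%04d", seq_len(nC))
    compounds <- data.frame(
      compound_id = ids,
      name = paste0("compound ", seq_len(nC)),
      MW = round(stats::runif(nC, 150, 700), 2),
      ALOGP = round(stats::runif(nC, -2, 7), 3),
      HBA = sample(0:14, nC, replace = TRUE),
      HBD = sample(0:8, nC, replace = TRUE),
      PSA = round(stats::runif(nC, 10, 200), 2),
      ROTB = sample(0:15, nC, replace = TRUE),
      AROM = sample(0:5, nC, replace = TRUE),
      ALERTS = sample(0:3, nC, replace = TRUE),
      stringsAsFactors = FALSE)
    targets <- c(sprintf("T%03d", seq_len(spec$n_targets - 1L)), "TPLANT")
    formula_ids <- ids[seq_len(spec$n_formula_compounds)]
    links <- do.call(rbind, lapply(targets, function(tg) {
      p <- rep(spec$link_density, nC)
      planted_here <- tg == "TPLANT" & ids %in% formula_ids &
        spec$enrichment_factor > 1
      p[planted_here] <- spec$enrichment_factor * spec$link_density
      hit <- stats::runif(nC) < p
      if (!any(hit)) return(NULL)
      score <- sample(150:999, sum(hit), replace = TRUE)
      score[planted_here[hit]] <- sample(400:999, sum(planted_here[hit]),
                                         replace = TRUE)
      data.frame(compound_id = ids[hit], target = tg, score = score,
                 stringsAsFactors = FALSE)
    }))
    bg_ids <- setdiff(ids, formula_ids)
    hc_links <- data.frame(
      herb_id = c(rep_len(c("HerbA", "HerbB", "HerbC"),
                          length(formula_ids)),
                  rep_len(sprintf("BGH%02d", 1:10), length(bg_ids))),
      compound_id = c(formula_ids, bg_ids),
      stringsAsFactors = FALSE)
    list(compounds = compounds, links = links, hc_links = hc_links,
         formula_compounds = formula_ids, planted_target = "TPLANT")
  })
}

#' Generate synthetic prescriptions with a planted core formula
#'
#' Each prescription includes the planted formula intact with probability
#' `presence_rate`, then noise herbs (`H01..`) sampled without replacement
#' until the prescription reaches a size drawn uniformly from
#' `[herbs_min, herbs_max]`. Noise herbs never coincide with planted
#' herbs, so the planted formula's support at high confidence equals its
#' presence rate up to binomial noise. Prescriptions are dealt to patients
#' round-robin with increasing visit ids.
#'
#' @param spec a [fixture_spec()].
#' @return a `prescription_dataset`.
#' @export
gen_prescriptions <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  pf <- spec$planted_formula
  if (spec$herbs_max > spec$n_herbs + length(pf))
    nf_stop("herbs_max exceeds the available herb pool")
  noise_pool <- sprintf("H%02d", seq_len(spec$n_herbs))
  with_seed(spec$seed, {
    n <- spec$n_prescriptions
    sizes <- sample(spec$herbs_min:spec$herbs_max, n, replace = TRUE)
    with_pf <- stats::runif(n) < spec$presence_rate
    herbs <- lapply(seq_len(n), function(i) {
      base <- if (with_pf[i]) pf else character(0)
      need <- max(sizes[i] - length(base), 1L)
      sort(c(base, sample(noise_pool, min(need, length(noise_pool)))))
    })
    pid <- sprintf("P%04d", ((seq_len(n) - 1L) %% spec$n_patients) + 1L)
    vid <- paste0("V", ((seq_len(n) - 1L) %/% spec$n_patients) + 1L)
    prescription_dataset(pid, vid, herbs)
  })
}

#' Generate a synthetic gene-set collection with a planted enriched term
#'
#' Terms `TERM01..` draw members uniformly from the gene universe; the
#' planted term `TERMPLANT` is overrepresented in the emitted query set by
#' `enrichment_factor` relative to its null expectation. At factor 1 the
#' query is drawn uniformly from the universe.
#'
#' @param spec a [fixture_spec()].
#' @return list with `gene_sets` (a `gene_set_collection`), `query`
#'   (character vector) and `planted_term`.
#' @export
gen_gene_sets <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_terms < 2L) nf_stop("n_terms must be >= 2")
  if (spec$term_size_max > spec$n_genes)
    nf_stop("term sizes must not exceed the gene universe")
  with_seed(spec$seed, {
    genes <- sprintf("g%05d", seq_len(spec$n_genes))
    sizes <- sample(spec$term_size_min:spec$term_size_max, spec$n_terms,
                    replace = TRUE)
    sets <- lapply(sizes, function(sz) sample(genes, sz))
    names(sets) <- c(sprintf("TERM%02d", seq_len(spec$n_terms - 1L)),
                     "TERMPLANT")
    planted <- sets[["TERMPLANT"]]
    q <- spec$query_size
    n_planted <- min(length(planted),
                     round(spec$enrichment_factor * q *
                             length(planted) / spec$n_genes))
    query <- if (spec$enrichment_factor > 1) {
      c(sample(planted, n_planted),
        sample(setdiff(genes, planted), q - n_planted))
    } else {
      sample(genes, q)
    }
    desc <- setNames(paste("synthetic term", seq_along(sets)), names(sets))
    list(gene_sets = gene_set_collection(sets, desc, universe = genes),
         query = sort(query), planted_term = "TERMPLANT")
  })
}
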