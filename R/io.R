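#' Read a compound descriptor table
#'
#' Loads the per-compound molecular descriptor table used for drug-likeness
#' screening. The CSV must carry a header with a `compound_id` column and
#' the eight descriptors `MW` (molecular weight, Da), `ALOGP` (octanol--
#' water logP), `HBA`/`HBD` (hydrogen-bond acceptor/donor counts), `PSA`
#' (polar surface area, A^2), `ROTB` (rotatable bonds), `AROM` (aromatic
#' rings) and `ALERTS` (structural alerts). An optional `name` column is
#' kept as free text.
#'
#' @param path path to a UTF-8 CSV file.
#' @return a `data.frame` with one row per compound.
#' @export
read_compound_table <- function(path) {
  df <- read_csv_checked(path)
  need <- c("compound_id", descriptor_names())
  miss <- setdiff(need, names(df))
  if (length(miss))
    nf_stop("compound table %s is missing column(s): %s", path,
            paste(miss, collapse = ", "))
  df$compound_id <- as.character(df$compound_id)
  if (anyDuplicated(df$compound_id)) {
    dup <- unique(df$compound_id[duplicated(df$compound_id)])
    nf_stop("duplicate compound_id value(s): %s", paste(dup, collapse = ", "))
  }
  for (col in descriptor_names()) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & trimws(as.character(raw)) != "")
    if (length(bad))
      nf_stop("non-numeric value '%s' in column %s at data row %d of %s",
              raw[bad[1L]], col, bad[1L], path)
    if (anyNA(val))
      nf_stop("missing value in column %s at data row %d of %s",
              col, which(is.na(val))[1L], path)
    df[[col]] <- val
  }
  if (any(df$MW <= 0)) nf_stop("MW must be positive for every compound")
  counts <- c("HBA", "HBD", "ROTB", "AROM", "ALERTS")
  if (any(as.matrix(df[counts]) < 0) || any(df$PSA < 0))
    nf_stop("descriptor counts and PSA must be non-negative")
  if (!"name" %in% names(df)) df$name <- NA_character_
  df[c("compound_id", "name", descriptor_names())]
}

descriptor_names <- function() {
  c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS")
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) nf_stop("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) nf_stop("file %s contains no data rows", path)
  df
}

#' Read a link table (herb-compound or scored compound-target)
#'
#' `kind = "herb_compound"` expects two columns (herb, compound); duplicate
#' pairs are collapsed and herb names are whitespace-normalized.
#' `kind = "compound_target"` expects two or three columns (compound,
#' target, optional association score on the 0--1000 scale). Rows without a
#' score receive the sentinel 9999, the convention for curated links that
#' carry no database score; duplicated pairs keep the maximum score.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param kind `"herb_compound"` or `"compound_target"`.
#' @return a `data.frame` with columns `herb_id`, `compound_id` or
#'   `compound_id`, `target`, `score`.
#' @export
read_links <- function(path, kind = c("herb_compound", "compound_target")) {
  kind <- match.arg(kind)
  df <- read_csv_checked(path)
  if (kind == "herb_compound") {
    if (ncol(df) < 2L) nf_stop("%s: herb-compound links need 2 columns", path)
    out <- data.frame(herb_id = normalize_herb(df[[1L]]),
                      compound_id = as.character(df[[2L]]),
                      stringsAsFactors = FALSE)
    out <- unique(out)
    rownames(out) <- NULL
    return(out)
  }
  if (ncol(df) < 2L) nf_stop("%s: compound-target links need 2-3 columns", path)
  score <- if (ncol(df) >= 3L) suppressWarnings(as.numeric(df[[3L]])) else
    rep(NA_real_, nrow(df))
  score[is.na(score)] <- 9999
  ok <- (score >= 0 & score <= 1000) | score == 9999
  if (!all(ok))
    nf_stop("%s: score %s outside [0,1000] or the 9999 sentinel at data row %d",
            path, format(score[!ok][1L]), which(!ok)[1L])
  out <- data.frame(compound_id = as.character(df[[1L]]),
                    target = as.character(df[[2L]]),
                    score = as.integer(score),
                    stringsAsFactors = FALSE)
  collapse_max_score(out)
}

# Duplicate (compound, target) pairs keep the maximum score -- conservative
# toward retaining associations.
collapse_max_score <- function(links) {
  key <- paste(links$compound_id, links$target, sep = "\r")
  if (anyDuplicated(key)) {
    mx <- tapply(links$score, key, max)
    first <- !duplicated(key)
    links <- links[first, , drop = FALSE]
    links$score <- as.integer(mx[paste(links$compound_id, links$target,
                                       sep = "\r")])
  }
  rownames(links) <- NULL
  links
}

#' Read prescription records
#'
#' Prescription data is a UTF-8 CSV with columns `Pid` (patient id), `Vid`
#' (visit id; use a constant when visits are not recorded) and `Herb`.
#' Both encodings are accepted: long format (one herb per row, grouped by
#' patient and visit) and wide format (the herb cell holds a
#' delimiter-separated list, default `";"`); the format is auto-detected by
#' the presence of the delimiter. Herb names are whitespace-trimmed and
#' deduplicated within a prescription.
#'
#' @param path path to the CSV file.
#' @param delim delimiter separating herbs in wide-format cells.
#' @return a `prescription_dataset` object.
#' @export
read_prescriptions <- function(path, delim = ";") {
  df <- read_csv_checked(path)
  nms <- tolower(names(df))
  idx <- match(c("pid", "vid", "herb"), nms)
  if (anyNA(idx))
    nf_stop("%s: prescription data needs columns Pid, Vid, Herb (missing: %s)",
            path, paste(c("Pid", "Vid", "Herb")[is.na(idx)], collapse = ", "))
  pid <- as.character(df[[idx[1L]]])
  vid <- as.character(df[[idx[2L]]])
  herb <- as.character(df[[idx[3L]]])

  wide <- any(grepl(delim, herb, fixed = TRUE))
  if (wide) {
    herbs <- lapply(strsplit(herb, delim, fixed = TRUE), clean_herbs)
    key_pid <- pid
    key_vid <- vid
  } else {
    key <- paste(pid, vid, sep = "\r")
    first <- !duplicated(key)
    herbs <- unname(lapply(split(herb, factor(key, levels = key[first])),
                           clean_herbs))
    key_pid <- pid[first]
    key_vid <- vid[first]
  }
  empty <- lengths(herbs) == 0L
  if (any(empty)) {
    i <- which(empty)[1L]
    nf_stop("prescription (%s, %s) has an empty herb set after cleaning",
            key_pid[i], key_vid[i])
  }
  if (wide && anyDuplicated(paste(key_pid, key_vid, sep = "\r")))
    nf_stop("duplicate (Pid, Vid) pairs in wide-format prescription data")
  prescription_dataset(key_pid, key_vid, herbs)
}

clean_herbs <- function(x) {
  x <- normalize_herb(x)
  sort(unique(x[nzchar(x)]))
}

#' Construct a prescription dataset
#'
#' @param pid,vid character vectors identifying patient and visit, one
#'   entry per prescription; `(pid, vid)` pairs must be unique.
#' @param herbs list of character vectors, the (deduplicated) herb set of
#'   each prescription.
#' @return an object of class `prescription_dataset` with elements `pid`,
#'   `vid`, `herbs`, `n_prescriptions` and `n_patients`.
#' @export
prescription_dataset <- function(pid, vid, herbs) {
  pid <- as.character(pid); vid <- as.character(vid)
  stopifnot(length(pid) == length(vid), length(pid) == length(herbs))
  if (anyDuplicated(paste(pid, vid, sep = "\r")))
    nf_stop("(Pid, Vid) pairs must be unique")
  herbs <- lapply(herbs, function(h) sort(unique(as.character(h))))
  if (any(lengths(herbs) == 0L)) nf_stop("every prescription needs >= 1 herb")
  structure(list(pid = pid, vid = vid, herbs = herbs,
                 n_prescriptions = length(pid),
                 n_patients = length(unique(pid))),
            class = "prescription_dataset")
}

#' @export
print.prescription_dataset <- function(x, ...) {
  cat(sprintf("<prescription_dataset> %d prescriptions, %d patients, %d herbs\n",
              x$n_prescriptions, x$n_patients,
              length(unique(unlist(x$herbs)))))
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT lines are tab-separated: term id, description, then one or more
#' gene ids. Lines with fewer than three fields are skipped with a warning;
#' the number skipped is recorded as `n_skipped`. The universe defaults to
#' the union of all member genes.
#'
#' @param path path to a GMT file.
#' @return a `gene_set_collection`: list with `sets` (named list of gene
#'   id vectors), `descriptions`, `universe` and `n_skipped`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) nf_stop("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) nf_stop("GMT file %s is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    nf_warn("skipped %d GMT line(s) with fewer than 3 fields", sum(short))
  fields <- fields[!short]
  if (!length(fields)) nf_stop("GMT file %s contains no usable gene sets", path)
  sets <- lapply(fields, function(f) sort(unique(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- names(sets)
  gene_set_collection(sets, desc, n_skipped = sum(short))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (term id -> member genes).
#' @param descriptions optional named character vector of term
#'   descriptions.
#' @param universe optional gene universe; defaults to the union of all
#'   sets. Every member gene must belong to it.
#' @param n_skipped number of malformed lines skipped at load time.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL,
                                n_skipped = 0L) {
  if (!length(sets) || is.null(names(sets)))
    nf_stop("'sets' must be a non-empty named list")
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (any(lengths(sets) == 0L)) nf_stop("every gene set must be non-empty")
  all_genes <- sort(unique(unlist(sets, use.names = FALSE)))
  universe <- if (is.null(universe)) all_genes else
    sort(unique(as.character(universe)))
  if (!all(all_genes %in% universe))
    nf_stop("every member gene must belong to the universe")
  if (is.null(descriptions)) {
    descriptions <- setNames(rep(NA_character_, length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = universe,
                 n_skipped = as.integer(n_skipped)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over %d genes (%d line(s) skipped)\n",
              length(x$sets), length(x$universe), x$n_skipped))
  invisible(x)
}

#' Read a protein-protein interaction network
#'
#' Expects a CSV or TSV edge list (auto-detected separator) whose first two
#' columns hold gene identifiers; extra columns are ignored. Self-loops and
#' duplicate or reversed-duplicate edges are removed, yielding a simple
#' undirected graph.
#'
#' @param path path to the edge-list file, header row required.
#' @return an undirected simple [igraph::graph] whose vertex names are the
#'   gene ids.
#' @export
read_ppi <- function(path) {
  if (!file.exists(path)) nf_stop("file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L || ncol(df) < 2L)
    nf_stop("PPI file %s contains no edges", path)
  a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
  keep <- a != b & nzchar(a) & nzchar(b)
  if (!any(keep)) nf_stop("PPI file %s has no valid (non-self) edge", path)
  g <- igraph::graph_from_data_frame(data.frame(a[keep], b[keep]),
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write tables and networks
#'
#' CSV writers mirror the corresponding readers so that any loaded table
#' round-trips; `write_ppi_edges()` emits a two-column edge list and
#' `export_graphml()` a GraphML file.
#'
#' @param x object to write (see the matching reader).
#' @param path output path.
#' @param graph an igraph object.
#' @param ds a `prescription_dataset`.
#' @param format `"long"` or `"wide"` prescription encoding.
#' @param delim herb delimiter used by the wide encoding.
#' @param gsc a `gene_set_collection`.
#' @return the output path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writers
#' @export
write_prescriptions <- function(ds, path, format = c("long", "wide"),
                                delim = ";") {
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(Pid = ds$pid, Vid = ds$vid,
                     Herb = vapply(ds$herbs, paste, "", collapse = delim),
                     stringsAsFactors = FALSE)
  } else {
    n <- lengths(ds$herbs)
    df <- data.frame(Pid = rep(ds$pid, n), Vid = rep(ds$vid, n),
                     Herb = unlist(ds$herbs), stringsAsFactors = FALSE)
  }
  write_table_csv(df, path)
}

#' @rdname writers
#' @export
write_gene_sets <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(tid) {
    d <- gsc$descriptions[[tid]]
    paste(c(tid, if (is.na(d)) "" else d, gsc$sets[[tid]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writers
#' @export
write_ppi_edges <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write_table_csv(data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                             stringsAsFactors = FALSE), path)
}

#' @rdname writers
#' @export
export_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Look up the herbs containing a compound
#'
#' Retrieval by chemical identity: given an InChIKey (e.g.
#' `ZYGHJZDHTFUPRJ-UHFFFAOYSA-N`) or a local compound id present in the
#' link table, returns every herb linked to that compound.
#'
#' @param key an InChIKey (14-10-1 uppercase block structure) or a
#'   compound id occurring in `hc_links`.
#' @param hc_links herb-compound links as returned by
#'   [read_links()].
#' @return character vector of herb ids (possibly empty).
#' @export
lookup_compound <- function(key, hc_links) {
  is_inchikey <- grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", key)
  if (!is_inchikey && !key %in% hc_links$compound_id)
    nf_stop("'%s' is neither a valid InChIKey nor a known compound id", key)
  sort(unique(hc_links$herb_id[hc_links$compound_id == key]))
}

#' Retrieve the compounds of a formula
#'
#' Maps a list of herbs to the union of their linked compounds. Herbs with
#' no links are reported with a warning; if none match, an error lists them
#' all.
#'
#' @param herbs character vector of herb names.
#' @param hc_links herb-compound links ([read_links()]).
#' @param compounds optional compound table ([read_compound_table()]); when
#'   given, matching descriptor rows are attached as the
#'   `"records"` attribute.
#' @return sorted character vector of compound ids.
#' @export
formula_compounds <- function(herbs, hc_links, compounds = NULL) {
  if (!length(herbs)) nf_stop("'herbs' must be non-empty")
  herbs <- normalize_herb(herbs)
  unmatched <- setdiff(herbs, hc_links$herb_id)
  if (length(unmatched) == length(unique(herbs)))
    nf_stop("no herb matched the link table: %s",
            paste(unmatched, collapse = ", "))
  if (length(unmatched))
    nf_warn("herb(s) not found in the link table: %s",
            paste(unmatched, collapse = ", "))
  ids <- sort(unique(hc_links$compound_id[hc_links$herb_id %in% herbs]))
  if (!is.null(compounds)) {
    attr(ids, "records") <- compounds[match(ids, compounds$compound_id), ,
                                      drop = FALSE]
  }
  ids
}
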