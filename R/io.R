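# Readers and writers for the pipeline's plain-text formats. All writers
# emit a "# key: value" metadata header (tool version, seed, thresholds);
# readers skip '#' lines, so write-then-read round-trips. No timestamps are
# written, so reruns are byte-identical.

meta_header <- function(meta = NULL) {
  lines <- sprintf("# geneconnectome %s",
                   as.character(utils::packageVersion("geneconnectome")))
  if (length(meta)) {
    lines <- c(lines, sprintf("# %s: %s", names(meta),
                              vapply(meta, function(v) paste(format(v), collapse = " "),
                                     character(1))))
  }
  lines
}

read_table_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- !grepl("^\\s*[#!]", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a gene-interaction edge list
#'
#' Parses a 3-column TSV (`gene_a`, `gene_b`, `confidence`); a header row is
#' optional, `#` comment lines are skipped, and CRLF files parse identically
#' to LF. Malformed rows and out-of-range confidences are reported with their
#' file line number.
#'
#' @param path file path.
#' @return data frame with columns `gene_a`, `gene_b`, `confidence`.
#' @export
read_edge_list <- function(path) {
  tl <- read_table_lines(path)
  parts <- strsplit(tl$lines, "[\t ]+")
  if (!length(parts)) stop("no edge rows in ", path)
  # optional header row, recognized by canonical column names
  f1 <- tolower(parts[[1L]][1L])
  f3 <- tolower(parts[[1L]][min(3L, length(parts[[1L]]))])
  if (f1 %in% c("gene_a", "gene", "from", "source") ||
      f3 %in% c("confidence", "conf", "weight", "score")) {
    parts <- parts[-1L]
    tl$lineno <- tl$lineno[-1L]
  }
  if (!length(parts)) stop("no edge rows in ", path)
  nf <- lengths(parts)
  bad <- which(nf < 3L)
  if (length(bad)) stop("malformed edge row (need 3 fields) at line ",
                        tl$lineno[bad[1L]], " of ", path)
  ga <- vapply(parts, `[`, character(1), 1L)
  gb <- vapply(parts, `[`, character(1), 2L)
  conf <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
  bad <- which(is.na(conf))
  if (length(bad)) stop("non-numeric confidence at line ", tl$lineno[bad[1L]],
                        " of ", path)
  bad <- which(conf <= 0 | conf > 1)
  if (length(bad)) stop("confidence outside (0, 1] at line ", tl$lineno[bad[1L]],
                        " of ", path)
  data.frame(gene_a = ga, gene_b = gb, confidence = conf,
             stringsAsFactors = FALSE)
}

#' Write a gene-interaction edge list
#'
#' @param x a `gene_network` or a data frame with columns `gene_a`, `gene_b`,
#'   `confidence`.
#' @param path output file path.
#' @param meta optional named list echoed into the `#` metadata header.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path, meta = NULL) {
  df <- if (inherits(x, "gene_network")) {
    direct_edges(x)[, c("gene_a", "gene_b", "confidence")]
  } else {
    x[, c("gene_a", "gene_b", "confidence")]
  }
  lines <- c(meta_header(meta), "gene_a\tgene_b\tconfidence",
             sprintf("%s\t%s\t%s", df$gene_a, df$gene_b,
                     format(df$confidence, digits = 15, trim = TRUE,
                            scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene set
#'
#' One symbol per line; `#` starts a comment (whole-line or trailing).
#' Symbols are normalized and deduplicated (a message reports collapsed
#' duplicates); an empty result is an error.
#'
#' @param path file path.
#' @param name set name (default: file name).
#' @return sorted character vector of symbols with attribute `set_name`.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  members <- normalize_symbol(lines)
  n_dup <- sum(duplicated(members))
  if (n_dup > 0L) message(n_dup, " duplicate symbol(s) collapsed in ", path)
  members <- sort(unique(members))
  if (!length(members)) stop("gene set is empty: ", path)
  attr(members, "set_name") <- name
  members
}

#' Write a gene set
#' @param genes character vector of symbols.
#' @param path output file path.
#' @param meta optional named list for the metadata header.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path, meta = NULL) {
  writeLines(c(meta_header(meta), sort(unique(normalize_symbol(genes)))), path)
  invisible(path)
}

#' Read gene-to-GO-term annotations
#'
#' Accepts either a two-column TSV (`gene`, `term_id`; optional header) or a
#' GAF 2.2 subset (lines starting with `!` skipped; gene symbol from column
#' 3, term id from column 5).
#'
#' @param path file path.
#' @return a `go_annotations` object.
#' @export
read_annotations <- function(path) {
  tl <- read_table_lines(path)
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (!length(parts)) stop("no annotation rows in ", path)
  if (length(parts[[1L]]) >= 15L) {
    gene <- vapply(parts, `[`, character(1), 3L)
    term <- vapply(parts, `[`, character(1), 5L)
  } else {
    if (any(lengths(parts) < 2L)) {
      stop("malformed annotation row at line ",
           tl$lineno[which(lengths(parts) < 2L)[1L]], " of ", path)
    }
    gene <- vapply(parts, `[`, character(1), 1L)
    term <- vapply(parts, `[`, character(1), 2L)
    if (tolower(gene[1L]) %in% c("gene", "symbol")) {
      gene <- gene[-1L]; term <- term[-1L]
    }
  }
  go_annotations(data.frame(gene = gene, term_id = term,
                            stringsAsFactors = FALSE))
}

#' Write gene-to-GO-term annotations as a two-column TSV
#' @param annotations a `go_annotations` object.
#' @param path output file path.
#' @param meta optional named list for the metadata header.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, meta = NULL) {
  stopifnot(inherits(annotations, "go_annotations"))
  df <- as.data.frame(annotations)
  writeLines(c(meta_header(meta), "gene\tterm_id",
               sprintf("%s\t%s", df$gene, df$term_id)), path)
  invisible(path)
}

#' Write a connectome (or candidate) table as TSV
#'
#' Distances are printed with 3 decimals and percentile p-values with 5, the
#' reporting precision used throughout; routes keep the `" <-> "` separator.
#'
#' @param x a `gene_connectome`, a `candidate_extraction`, or a data frame
#'   with the corresponding columns.
#' @param path output file path.
#' @param meta optional named list for the metadata header.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path, meta = NULL) {
  if (inherits(x, "gene_connectome")) {
    meta <- c(list(core = x$core, n_ref = x$n_ref,
                   n_ref_policy = x$n_ref_policy), meta)
    df <- x$entries
  } else if (inherits(x, "candidate_extraction")) {
    meta <- c(list(alpha = x$alpha), as.list(x$funnel), meta)
    df <- x$candidates
  } else {
    df <- x
  }
  num <- vapply(df, is.numeric, logical(1))
  fmt <- df
  for (col in names(df)[num]) {
    fmt[[col]] <- if (col == "p") {
      sprintf("%.5f", df[[col]])
    } else if (col %in% c("distance", "observed_median")) {
      sprintf("%.3f", df[[col]])
    } else {
      format(df[[col]], trim = TRUE, scientific = FALSE)
    }
  }
  lines <- c(meta_header(meta), paste(names(fmt), collapse = "\t"),
             do.call(paste, c(unname(as.list(fmt)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic world to standard pipeline input files
#'
#' Writes `edges.tsv`, `core.txt`, `holdout.txt`, `annotations.tsv`,
#' `modules.tsv` and a `params.json` sidecar recording the generator
#' parameters and seed.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             core = file.path(dir, "core.txt"),
             holdout = file.path(dir, "holdout.txt"),
             annotations = file.path(dir, "annotations.tsv"),
             modules = file.path(dir, "modules.tsv"),
             params = file.path(dir, "params.json"))
  meta <- list(seed = world$seed)
  write_edge_list(world$network, paths[["edges"]], meta = meta)
  write_gene_set(world$core, paths[["core"]], meta = meta)
  write_gene_set(world$holdout, paths[["holdout"]], meta = meta)
  write_annotations(world$annotations, paths[["annotations"]], meta = meta)
  writeLines(c(meta_header(meta), "gene\tmodule",
               sprintf("%s\t%d", names(world$module_of), world$module_of)),
             paths[["modules"]])
  jsonlite::write_json(world$params, paths[["params"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
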