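#' Read / write tab-separated expression matrices
#'
#' Matrices are stored with the feature id in the first column and sample
#' ids in the header.
#'
#' @param path file path.
#' @param mat features x samples numeric matrix.
#' @name matrix_tsv
NULL

#' @rdname matrix_tsv
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write a GMT target annotation
#'
#' One line per miRNA: id, a description field, then the target gene ids.
#'
#' @param target_db a `target_db` list (targets, universe).
#' @param path file path.
#' @param universe gene universe to attach on read (default: union of the
#'   sets).
#' @name gmt
NULL

#' @rdname gmt
#' @export
write_gmt <- function(target_db, path) {
  lines <- vapply(names(target_db$targets), function(m)
    paste(c(m, "targetome", target_db$targets[[m]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  targets <- lapply(parts, function(p)
    if (length(p) > 2) p[-(1:2)] else character(0))
  names(targets) <- vapply(parts, `[`, character(1), 1)
  if (is.null(universe)) universe <- sort(unique(unlist(targets)))
  structure(list(targets = targets, universe = universe),
            class = "target_db")
}

#' Read / write a network as a two-column SIF-style edge list
#'
#' @param g an igraph graph.
#' @param path file path.
#' @name sif
NULL

#' @rdname sif
#' @export
write_sif <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(source = el[, 1], interaction = "pp", target = el[, 2],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname sif
#' @export
read_sif <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  el <- if (ncol(df) >= 3) df[, c(1, 3)] else df[, 1:2]
  igraph::graph_from_data_frame(el, directed = FALSE)
}

#' Write BED6+2 mapped reads (mismatches, n_alignments as extra columns)
#'
#' @param reads read data.frame from [generate_read_set()].
#' @param path file path.
#' @export
write_reads_bed <- function(reads, path) {
  write.table(reads[, c("contig", "start", "end", "name", "score",
                        "strand", "mismatches", "n_alignments")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read BED6+2 mapped reads
#'
#' @param path file path.
#' @export
read_reads_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("contig", "start", "end", "name", "score", "strand",
                 "mismatches", "n_alignments")
  df
}

#' Write all inputs of a synthetic study to a directory
#'
#' Writes the gene and miRNA matrices and the sample sheet as TSV, the
#' target annotation as GMT, the PPI as SIF, and the ground truth as a
#' JSON sidecar.
#'
#' @param study,truth from [generate_study()].
#' @param target_db,ppi annotations.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_study_inputs <- function(study, truth, target_db, ppi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(study$gene_matrix, file.path(dir, "genes.tsv"))
  write_matrix_tsv(study$mirna_matrix, file.path(dir, "mirnas.tsv"))
  write.table(study$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(as.character(c(study$negctrl_mean, study$negctrl_sd)),
             file.path(dir, "negctrl.txt"))
  write_gmt(target_db, file.path(dir, "targets.gmt"))
  write_sif(ppi, file.path(dir, "ppi.sif"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read the inputs written by [write_study_inputs()]
#'
#' @param dir input directory.
#' @return list(study, target_db, ppi, truth).
#' @export
read_study_inputs <- function(dir) {
  samples <- read.delim(file.path(dir, "samples.tsv"),
                        stringsAsFactors = FALSE)
  ng <- as.numeric(readLines(file.path(dir, "negctrl.txt")))
  study <- structure(
    list(gene_matrix = read_matrix_tsv(file.path(dir, "genes.tsv")),
         mirna_matrix = read_matrix_tsv(file.path(dir, "mirnas.tsv")),
         samples = samples, negctrl_mean = ng[1], negctrl_sd = ng[2]),
    class = "expression_study")
  target_db <- read_gmt(file.path(dir, "targets.gmt"),
                        universe = rownames(study$gene_matrix))
  ppi <- read_sif(file.path(dir, "ppi.sif"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(study = study, target_db = target_db, ppi = ppi, truth = truth)
}
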