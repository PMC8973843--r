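# Readers/writers for the plain-text formats the pipeline consumes:
# gene-effect / probability / expression TSVs (genes as rows, sample-ID
# header), BED3+ and BEDPE interval tables (0-based half-open), and the
# long-format activity and puncta TSVs.

#' Read a genes-by-samples matrix from TSV
#'
#' First column = gene IDs, remaining columns = samples.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write a genes-by-samples matrix to TSV
#'
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param id_col name for the gene-ID column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  data.table::fwrite(cbind(dt, data.table::as.data.table(m)), path,
                     sep = "\t")
  invisible(path)
}

#' Read a gene-effect screen from TSV files
#'
#' @param effects_path,prob_path genes x samples TSVs (shared layout).
#' @param annot_path sample annotation TSV with columns `sample`,
#'   `lineage` and logical `subtype`.
#' @return a `gene_effect_matrix`.
#' @export
read_gene_effect <- function(effects_path, prob_path, annot_path) {
  eff <- read_matrix_tsv(effects_path)
  prob <- read_matrix_tsv(prob_path)
  ann <- as.data.frame(data.table::fread(annot_path, sep = "\t"))
  gene_effect_matrix(eff, prob[rownames(eff), colnames(eff), drop = FALSE],
                     ann[match(colnames(eff), ann$sample), , drop = FALSE])
}

#' Read/write BEDPE loop tables
#'
#' Columns: chrom_a, start_a, end_a, chrom_b, start_b, end_b, name (loop
#' id), score (contact frequency); coordinates 0-based half-open.
#'
#' @param path file path.
#' @return data.frame with `loop_id` and `frequency` columns.
#' @export
read_bedpe <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  names(dt)[1:8] <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                      "end_b", "loop_id", "frequency")
  dt
}

#' @rdname read_bedpe
#' @param loops loop data.frame as produced by [sim_regulatory_locus()].
#' @export
write_bedpe <- function(loops, path) {
  data.table::fwrite(loops[, c("chrom_a", "start_a", "end_a", "chrom_b",
                               "start_b", "end_b", "loop_id", "frequency")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ interval table
#'
#' @param path file path; first three columns chrom/start/end (0-based
#'   half-open), optional fourth = name, fifth = score.
#' @return data.frame with standard column names.
#' @export
read_bed <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(dt)[seq_len(min(ncol(dt), 6))] <- nm[seq_len(min(ncol(dt), 6))]
  dt
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally more
#'   columns, written in order.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
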