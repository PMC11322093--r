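#' Linkage-disequilibrium reference panel
#'
#' A symmetric matrix of squared allele-dosage correlations (r²) with unit
#' diagonal plus per-SNP genomic positions, standing in for the external LD
#' reference (e.g. a 1000 Genomes panel) that clumping requires.
#'
#' @param snp_ids character vector of SNP identifiers.
#' @param r2 symmetric numeric matrix of squared correlations in `[0, 1]`,
#'   one row/column per SNP, diagonal exactly 1.
#' @param positions data frame with columns `snp_id`, `chrom`, `pos`.
#' @return an object of class `ld_panel`.
#' @export
ld_panel <- function(snp_ids, r2, positions) {
  snp_ids <- as.character(snp_ids)
  stopifnot(is.matrix(r2), nrow(r2) == length(snp_ids),
            ncol(r2) == length(snp_ids))
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix not symmetric", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("r2 diagonal must be 1", call. = FALSE)
  if (min(r2) < -1e-8 || max(r2) > 1 + 1e-8) {
    stop("r2 entries must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(is.data.frame(positions),
            all(c("snp_id", "chrom", "pos") %in% names(positions)))
  positions <- positions[match(snp_ids, positions$snp_id), ]
  if (anyNA(positions$snp_id)) {
    stop("positions missing for some panel SNPs", call. = FALSE)
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  positions$chrom <- as.character(positions$chrom)
  rownames(positions) <- NULL
  structure(list(snp_ids = snp_ids, r2 = r2, positions = positions),
            class = "ld_panel")
}

#' @rdname ld_panel
#' @param x an `ld_panel`.
#' @param ... unused.
#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("ld_panel: %d SNPs, %d chromosome(s)\n",
              length(x$snp_ids), length(unique(x$positions$chrom))))
  invisible(x)
}

#' Read / write an LD panel as delimited text
#'
#' The matrix file holds the r² matrix with a header row of SNP ids; the
#' positions file is a 3-column table (`snp_id`, `chrom`, `pos`).
#'
#' @param matrix_path,positions_path file paths.
#' @param sep field separator.
#' @return for the reader, an [ld_panel]; for the writer, `matrix_path`
#'   invisibly.
#' @export
read_ld_panel <- function(matrix_path, positions_path, sep = "\t") {
  m <- as.matrix(read.table(matrix_path, header = TRUE, sep = sep,
                            check.names = FALSE))
  pos <- read.table(positions_path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
  ld_panel(colnames(m), unname(m), pos)
}

#' @rdname read_ld_panel
#' @param panel an [ld_panel].
#' @export
write_ld_panel <- function(panel, matrix_path, positions_path, sep = "\t") {
  stopifnot(inherits(panel, "ld_panel"))
  write.table(panel$r2, matrix_path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = panel$snp_ids)
  write.table(panel$positions, positions_path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}
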