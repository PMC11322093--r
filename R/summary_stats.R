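#' GWAS summary statistics for one trait
#'
#' Container for per-SNP association records of a single trait. Construction
#' validates every record and drops rows that violate the invariants (single
#' A/C/G/T alleles, effect allele different from the other allele, strictly
#' positive standard error, effect-allele frequency in (0,1) when present,
#' p-value in (0,1]); the counts of dropped rows are kept in a load report.
#' Missing p-values are back-filled from `beta/se` by the two-sided normal
#' approximation, the GWAS convention at these sample sizes. Duplicate SNP
#' identifiers keep the row with the smallest p-value.
#'
#' @param records data frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` (required) and `chrom`, `pos`, `eaf`,
#'   `pval`, `n` (optional).
#' @param trait_id text label for the trait.
#' @param sample_size trait-level default sample size, used where a record
#'   has no `n`.
#' @return an object of class `summary_stats`: a list with elements
#'   `trait_id`, `records` (validated data frame in canonical column order),
#'   `sample_size`, and `load_report` (list with `n_input`, `n_dropped`,
#'   and a per-reason `reasons` table).
#' @seealso [read_summary_stats()], [write_summary_stats()], [harmonize()]
#' @export
summary_stats <- function(records, trait_id, sample_size = NULL) {
  stopifnot(is.data.frame(records))
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(required, names(records))
  if (length(miss)) {
    stop("summary statistics lack required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  optional <- c("chrom", "pos", "eaf", "pval", "n")
  for (col in optional) if (!col %in% names(records)) records[[col]] <- NA
  records <- records[c("snp_id", "chrom", "pos", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pval", "n")]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  n_input <- nrow(records)
  reasons <- character(0)
  drop_with <- function(bad, why) {
    if (any(bad)) {
      reasons <<- c(reasons, rep(why, sum(bad)))
      records <<- records[!bad, , drop = FALSE]
    }
  }
  bases <- c("A", "C", "G", "T")
  drop_with(is.na(records$snp_id) | records$snp_id == "", "missing snp_id")
  drop_with(!(records$effect_allele %in% bases) |
              !(records$other_allele %in% bases),
            "non-biallelic-SNP alleles")
  drop_with(records$effect_allele == records$other_allele,
            "effect allele equals other allele")
  drop_with(!is.finite(records$beta), "missing/non-finite beta")
  drop_with(!is.finite(records$se) | records$se <= 0, "se not positive")
  drop_with(!is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1),
            "eaf outside (0,1)")
  drop_with(!is.na(records$pval) & (records$pval <= 0 | records$pval > 1),
            "pval outside (0,1]")
  drop_with(!is.na(records$pos) & records$pos < 0, "negative position")

  # back-fill p from beta/se; fill record n from the trait default
  fill <- is.na(records$pval)
  records$pval[fill] <- two_sided_p(records$beta[fill], records$se[fill])
  if (!is.null(sample_size) && anyNA(records$n)) {
    records$n[is.na(records$n)] <- sample_size
  }

  # duplicate identifiers: keep the smallest-p row
  if (anyDuplicated(records$snp_id)) {
    o <- order(records$snp_id, records$pval)
    records <- records[o, , drop = FALSE]
    dup <- duplicated(records$snp_id)
    reasons <- c(reasons, rep("duplicate snp_id (larger p)", sum(dup)))
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL

  if (nrow(records) == 0) {
    stop("no records survived validation for trait '", trait_id, "'",
         call. = FALSE)
  }
  structure(
    list(trait_id = trait_id,
         records = records,
         sample_size = sample_size,
         load_report = list(
           n_input = n_input,
           n_dropped = length(reasons),
           reasons = table(reasons))),
    class = "summary_stats"
  )
}

#' @rdname summary_stats
#' @param x a `summary_stats` object.
#' @param ... unused.
#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: trait '%s', %d SNPs (%d of %d input rows dropped)\n",
              x$trait_id, nrow(x$records), x$load_report$n_dropped,
              x$load_report$n_input))
  invisible(x)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table with a header, renames columns via
#' `column_map`, and validates it through [summary_stats()].
#'
#' @param path file path.
#' @param trait_id trait label.
#' @param column_map named character vector mapping canonical names
#'   (`snp_id`, `effect_allele`, `other_allele`, `beta`, `se`, and optionally
#'   `chrom`, `pos`, `eaf`, `pval`, `n`) to the file's column names.
#'   `NULL` assumes canonical names already.
#' @param sample_size trait-level default sample size.
#' @param sep field separator; guessed from the header line when `NULL`.
#' @return a [summary_stats] object.
#' @export
read_summary_stats <- function(path, trait_id, column_map = NULL,
                               sample_size = NULL, sep = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(tab))
    if (length(absent)) {
      stop("mapped columns absent from file: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    for (canon in names(column_map)) {
      names(tab)[names(tab) == column_map[[canon]]] <- canon
    }
  }
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("file lacks required columns (after mapping): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  summary_stats(tab, trait_id = trait_id, sample_size = sample_size)
}

#' Write summary statistics in canonical column order
#'
#' @param ss a [summary_stats] object.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ss, path, sep = "\t") {
  stopifnot(inherits(ss, "summary_stats"))
  write.table(ss$records, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a harmonized exposure/outcome set
#'
#' Emits the retained rows (paired columns for both traits) followed by a
#' second table of dropped SNPs with their reasons when `dropped_path` is
#' given.
#'
#' @param h a [harmonize()] result.
#' @param path output file path for retained rows.
#' @param dropped_path optional path for the dropped-SNP table.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_harmonized_set <- function(h, path, dropped_path = NULL, sep = "\t") {
  stopifnot(inherits(h, "harmonized_set"))
  write.table(h$rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(dropped_path)) {
    write.table(h$dropped, dropped_path, sep = sep, quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
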