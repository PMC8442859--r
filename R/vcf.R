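#' Write a synthetic dataset as VCF plus sample metadata
#'
#' Serialises dosages to an uncompressed VCFv4.2 file with unphased
#' diploid genotypes (0/0, 0/1, 1/1, ./.) on a single synthetic contig at
#' 1-based positions 1..L, and writes a tab-separated sidecar table
#' (columns \code{sample_id}, \code{cohort}) carrying the cohort labels.
#'
#' @param dataset A \code{synth_dataset} (or a list with \code{geno} and
#'   \code{cohorts}).
#' @param path Output VCF path; the metadata table goes to
#'   \code{meta_path}.
#' @param meta_path Sidecar TSV path (default: \code{path} with extension
#'   replaced by \code{.samples.tsv}).
#' @return Invisibly, a list with the two paths.
#' @seealso [read_vcf()]
#' @export
write_vcf <- function(dataset, path, meta_path = NULL) {
  stopifnot(is.list(dataset), !is.null(dataset$geno), !is.null(dataset$cohorts))
  geno <- dataset$geno
  if (is.null(rownames(geno))) stop("genotype matrix must have sample ids as rownames", call. = FALSE)
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.vcf$", "", path), ".samples.tsv")
  L <- ncol(geno)
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = L, ncol = nrow(geno))
  obs <- !is.na(t(geno)) # L x n
  gt[obs] <- gt_codes[t(geno)[obs] + 1L]
  body <- paste(
    "chrSyn", seq_len(L), paste0("snp", seq_len(L)), "A", "C", ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrSyn,length=%d>", L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", rownames(geno)),
      collapse = "\t"
    )
  )
  writeLines(c(header, body), path)
  utils::write.table(
    data.frame(sample_id = rownames(geno), cohort = unname(dataset$cohorts[rownames(geno)])),
    meta_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(list(vcf = path, meta = meta_path))
}

#' Read a VCF and its cohort metadata into a dosage matrix
#'
#' Parses a diploid biallelic VCF (via \pkg{vcfR}) into an integer
#' alt-allele dosage matrix (individuals x loci, \code{NA} for ./.) and
#' attaches cohort labels from the sidecar sample table. Multiallelic
#' records are rejected with the offending record named; samples present
#' in the VCF but absent from the metadata are an error.
#'
#' @param path VCF path.
#' @param meta_path Sidecar TSV (columns sample_id, cohort); default
#'   derived from \code{path} as in [write_vcf()].
#' @return List with \code{geno} (integer matrix, rownames = sample ids)
#'   and \code{cohorts} (named character vector).
#' @export
read_vcf <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.vcf$", "", path), ".samples.tsv")
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    r <- which(multi)[1L]
    stop(sprintf(
      "multiallelic record not supported: %s:%s (ID %s, ALT %s)",
      v@fix[r, "CHROM"], v@fix[r, "POS"], v@fix[r, "ID"], alt[r]
    ), call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
    dimnames = list(colnames(gt), rownames(gt))
  )
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  gtv <- t(gt)
  known <- gtv %in% names(lookup)
  bad <- !known & !is.na(gtv) & !(gtv %in% c("./.", ".|.", "."))
  if (any(bad)) stop("unrecognised GT value(s): ", paste(unique(gtv[bad])[1:3], collapse = ", "), call. = FALSE)
  dos[known] <- lookup[gtv[known]]
  if (!file.exists(meta_path)) stop("sample metadata table not found: ", meta_path, call. = FALSE)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cohort") %in% names(meta))) {
    stop("metadata must have columns sample_id and cohort", call. = FALSE)
  }
  missing_meta <- setdiff(rownames(dos), meta$sample_id)
  if (length(missing_meta)) {
    stop("samples in VCF missing from metadata: ", paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(meta$cohort) | meta$cohort == "")) {
    stop("empty cohort label in sample metadata", call. = FALSE)
  }
  cohorts <- stats::setNames(meta$cohort, meta$sample_id)[rownames(dos)]
  list(geno = dos, cohorts = cohorts)
}
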