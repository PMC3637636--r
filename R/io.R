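# Readers and writers for the two genotype interchange formats: plain
# matrix TSV (canonical) and the PLINK .raw additive dialect.

#' Write a genotype dataset
#'
#' Two formats are supported.  `"tsv"`: a `#`-prefixed provenance
#' header, then a header row (`subject_id`, `phenotype`, SNP ids) and
#' one row per subject; phenotype coded 0/1, missing genotypes as
#' `NA`.  SNP-id prefixes (`inf_`, `rnd_`, `dif_`, `cau_`) encode the
#' SNP roles so a round-trip preserves them.  `"plink_raw"`: the PLINK
#' `--recode A` additive dialect (`FID IID PAT MAT SEX PHENOTYPE` then
#' `<snp>_A` dosage columns, phenotype coded 1=control/2=case).
#'
#' @param dataset a `genotype_dataset`.
#' @param path output file.
#' @param format `"tsv"` or `"plink_raw"`.
#' @export
write_genotypes <- function(dataset, path,
                            format = c("tsv", "plink_raw")) {
  format <- match.arg(format)
  G <- dataset$genotypes
  subj <- rownames(G)
  if (is.null(subj)) subj <- sprintf("subj_%04d", seq_len(nrow(G)))
  if (format == "tsv") {
    dt <- data.table::data.table(subject_id = subj,
                                 phenotype = dataset$phenotype)
    dt <- cbind(dt, data.table::as.data.table(G))
    writeLines(sprintf("# robustps %s | %d subjects | %d SNPs",
                       as.character(utils::packageVersion("robustps")),
                       nrow(G), ncol(G)), path)
    data.table::fwrite(dt, path, sep = "\t", append = TRUE,
                       col.names = TRUE, na = "NA")
  } else {
    dt <- data.table::data.table(FID = subj, IID = subj, PAT = 0L,
                                 MAT = 0L, SEX = 0L,
                                 PHENOTYPE = dataset$phenotype + 1L)
    Gm <- G
    colnames(Gm) <- paste0(colnames(G), "_A")
    dt <- cbind(dt, data.table::as.data.table(Gm))
    data.table::fwrite(dt, path, sep = " ", na = "NA")
  }
  invisible(path)
}

role_from_id <- function(ids) {
  pre <- substr(ids, 1, 4)
  role <- c(inf_ = "inference", rnd_ = "random", dif_ = "differentiated",
            cau_ = "causal")[pre]
  role[is.na(role)] <- "inference"
  unname(role)
}

#' Read a genotype dataset
#'
#' Inverse of [write_genotypes()].  Genotype tokens must be numeric in
#' `[0, 2]` (integer calls or real-valued dosages) or `NA`; anything
#' else raises a parse error naming the offending row and column.
#' PLINK phenotypes 1/2 are decoded to 0/1; SNP roles are recovered
#' from the id prefixes where present, defaulting to `inference`.
#'
#' @param path input file.
#' @param format `"tsv"` or `"plink_raw"`; `NULL` guesses from the
#'   extension (`.raw` implies PLINK).
#' @return A `genotype_dataset`.
#' @export
read_genotypes <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.raw$", path)) "plink_raw" else "tsv"
  format <- match.arg(format, c("tsv", "plink_raw"))
  first <- readLines(path, n = 50L)
  if (length(first) == 0 || all(!nzchar(first)))
    stop("empty file: ", path)
  skip <- sum(cumprod(startsWith(first, "#")))
  dt <- data.table::fread(path, skip = skip, sep = "auto",
                          header = TRUE, na.strings = "NA",
                          data.table = FALSE)
  if (nrow(dt) == 0) stop("no subject rows in ", path)
  if (format == "tsv") {
    need <- c("subject_id", "phenotype")
    if (!all(need %in% names(dt)))
      stop("malformed TSV header: need subject_id and phenotype columns")
    subj <- as.character(dt$subject_id)
    phen <- dt$phenotype
    if (anyNA(phen) || !all(phen %in% c(0, 1)))
      stop("phenotype must be coded 0/1 without missing values")
    Gcols <- setdiff(names(dt), need)
    snp_ids <- Gcols
  } else {
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(dt)))
      stop("malformed .raw header: need the six PLINK columns")
    subj <- as.character(dt$IID)
    phen <- dt$PHENOTYPE
    if (anyNA(phen) || !all(phen %in% c(1, 2)))
      stop("PLINK phenotype must be coded 1/2 without missing values")
    phen <- as.integer(phen - 1L)
    Gcols <- setdiff(names(dt), need)
    snp_ids <- sub("_[ACGT0-9]+$", "", Gcols)
  }
  G <- as.matrix(dt[, Gcols, drop = FALSE])
  if (!is.numeric(G)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(G), nrow(G)))) & !is.na(G), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric genotype at row %d, column %s", bad[1],
                 Gcols[bad[2]]))
  }
  oob <- which(!is.na(G) & (G < 0 | G > 2), arr.ind = TRUE)
  if (nrow(oob) > 0)
    stop(sprintf("genotype out of [0, 2] at row %d, column %s",
                 oob[1, 1], Gcols[oob[1, 2]]))
  dimnames(G) <- list(subj, snp_ids)
  phen <- as.integer(phen)
  meta <- data.frame(subject = subj, phenotype = phen, outlier = FALSE,
                     stringsAsFactors = FALSE)
  new_genotype_dataset(G, phen, role_from_id(snp_ids), meta,
                       snp_freqs = NULL, scenario = NULL)
}
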