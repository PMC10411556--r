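#' Read and write genotype matrices
#'
#' Genotypes travel as delimited text: individuals in rows, an `id` column
#' first, then one 0/1/2 dosage column per SNP (missing = empty or `NA`).
#' The PLINK RAW dialect (`FID IID PAT MAT SEX PHENOTYPE` then allele-dosage
#' columns, as written by `plink --recode A`) is also accepted on read.
#'
#' @param path File path (`.csv` or `.tsv`/`.txt`/`.raw`; delimiter inferred).
#' @param format `"auto"`, `"table"` (id + dosage columns) or `"plink_raw"`.
#' @return An integer genotype matrix with ids as rownames.
#' @export
read_genotypes <- function(path, format = c("auto", "table", "plink_raw")) {
  format <- match.arg(format)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else NULL
  d <- if (is.null(delim)) {
    readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE)
  }
  plink_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  is_plink <- format == "plink_raw" ||
    (format == "auto" && all(plink_cols %in% names(d)))
  if (is_plink) {
    ids <- as.character(d$IID)
    G <- as.matrix(d[, setdiff(names(d), plink_cols), drop = FALSE])
  } else {
    ids <- as.character(d[[1]])
    G <- as.matrix(d[, -1, drop = FALSE])
  }
  storage.mode(G) <- "integer"
  rownames(G) <- ids
  G
}

#' @rdname read_genotypes
#' @param geno Genotype matrix to write.
#' @param plink_raw Write the PLINK RAW dialect instead of the plain table.
#' @export
write_genotypes <- function(geno, path, plink_raw = FALSE) {
  if (plink_raw) {
    d <- tibble(FID = rownames(geno), IID = rownames(geno),
                PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L)
    d <- dplyr::bind_cols(d, as_tibble(geno))
    readr::write_delim(d, path, delim = " ")
  } else {
    d <- dplyr::bind_cols(tibble(id = rownames(geno)), as_tibble(geno))
    readr::write_csv(d, path)
  }
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Phenotypes are CSV/TSV with columns `id`, `generation`, `trait_*` and
#' optionally `rel_*` (reliabilities) and `tbv_*` (simulated true breeding
#' values).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  d$id <- as.character(d$id)
  d
}

#' @rdname read_phenotypes
#' @param phenotypes Tibble to write.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' Read and write square matrices (kernels, distances) as TSV
#'
#' Layout: a header row of ids, an id column first — readable back into R or
#' any other environment.
#'
#' @param m Symmetric matrix with ids as dimnames.
#' @param path File path.
#' @export
write_kernel <- function(m, path) {
  d <- dplyr::bind_cols(tibble(id = rownames(m) %||% as.character(seq_len(nrow(m)))),
                        as_tibble(m, .name_repair = "minimal"))
  readr::write_tsv(d, path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  m
}

#' Serialize a fitted SVR model to a plain-text file pair
#'
#' Writes the dual solution (training ids, net multipliers, bias,
#' hyperparameters) as TSV — sufficient to re-predict with kernel rows
#' against the stored training ids, without refitting.
#'
#' @param model An `mtsvr_svr` or `mtsvr_qmtsvr`.
#' @param path Output TSV path.
#' @export
write_svr_model <- function(model, path) {
  svr <- if (inherits(model, "mtsvr_qmtsvr")) model$svr else model
  hdr <- sprintf("# b0=%.17g C=%.17g epsilon=%.17g", svr$b0, svr$cost,
                 svr$epsilon)
  body <- tibble(id = svr$ids %||% as.character(seq_along(svr$beta)),
                 beta = svr$beta)
  writeLines(hdr, path)
  readr::write_tsv(body, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
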