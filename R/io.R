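#' Read a genotype matrix from VCF or TSV
#'
#' VCF input (v4.2, 1-based positions) is parsed with vcfR; only biallelic
#' SNP records are used (others are skipped with a warning), `./.` becomes
#' `NA`, and genotypes are coded as alternate-allele counts. The TSV
#' dialect is a plain table with individuals as rows, loci as columns and
#' cells in `{0, 1, 2, NA}`.
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension by
#'   default.
#' @param pop optional factor/character of population labels (`pop0` /
#'   `pop1`), one per individual, turning the result into a two-population
#'   `ref_panel`.
#' @param meta optional path to a tab-separated locus-metadata sidecar
#'   with columns `locus_id`, `tag_length`, `snp_pos`.
#' @return a `ref_panel` (with a single-level `pop` factor when `pop` is
#'   not given); `loci` carries `snp_pos`/`tag_length` from `meta` or from
#'   the VCF `POS` column, and the number of skipped non-biallelic records
#'   is in `attr(, "n_skipped")`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           pop = NULL, meta = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop_param("file not found: ", path)

  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fixed <- vcfR::getFIX(v)
    if (is.null(dim(fixed))) fixed <- matrix(fixed, nrow = 1,
                                             dimnames = list(NULL, names(fixed)))
    ref <- fixed[, "REF"]
    alt <- fixed[, "ALT"]
    biallelic <- !is.na(ref) & !is.na(alt) &
      nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt)
    n_skipped <- sum(!biallelic)
    if (n_skipped) {
      warning(n_skipped, " non-biallelic-SNP record(s) skipped", call. = FALSE)
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[biallelic, , drop = FALSE]
    fixed <- fixed[biallelic, , drop = FALSE]
    ids <- fixed[, "ID"]
    no_id <- is.na(ids) | ids == "."
    ids[no_id] <- paste0(fixed[no_id, "CHROM"], "_", fixed[no_id, "POS"])
    if (anyDuplicated(ids)) stop_param("duplicated locus ids in VCF")
    code <- function(x) {
      x <- gsub("\\|", "/", x)
      out <- rep(NA_integer_, length(x))
      out[x %in% c("0/0")] <- 0L
      out[x %in% c("0/1", "1/0")] <- 1L
      out[x %in% c("1/1")] <- 2L
      out
    }
    geno <- t(apply(gt, 2, code))
    if (nrow(gt) == 1) geno <- matrix(as.integer(geno), ncol = 1)
    storage.mode(geno) <- "integer"
    colnames(geno) <- ids
    rownames(geno) <- colnames(gt)
    loci <- data.frame(locus_id = ids,
                       tag_length = NA_integer_,
                       snp_pos = as.integer(fixed[, "POS"]),
                       stringsAsFactors = FALSE)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE)
    geno <- as.matrix(tab)
    storage.mode(geno) <- "integer"
    check_genotype_codes(geno, "TSV genotypes")
    loci <- data.frame(locus_id = colnames(geno),
                       tag_length = NA_integer_, snp_pos = NA_integer_,
                       stringsAsFactors = FALSE)
    n_skipped <- 0L
  }

  if (!is.null(meta)) {
    m <- read.table(meta, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    i <- match(loci$locus_id, m$locus_id)
    loci$tag_length <- as.integer(m$tag_length[i])
    loci$snp_pos <- as.integer(m$snp_pos[i])
  }

  pop <- if (is.null(pop)) {
    factor(rep("pop0", nrow(geno)), levels = c("pop0", "pop1"))
  } else {
    if (length(pop) != nrow(geno)) stop_param("pop must label every individual")
    factor(pop, levels = c("pop0", "pop1"))
  }
  panel <- structure(list(geno = geno, pop = pop, loci = loci, truth = NULL),
                     class = "ref_panel")
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal plain-text VCF: one biallelic SNP record per locus
#' (CHROM = locus id, POS = SNP position within the tag, REF = A,
#' ALT = C), genotypes `0/0`, `0/1`, `1/1`, missing `./.`.
#'
#' @param geno individuals x loci genotype matrix.
#' @param path output file.
#' @param loci optional locus data frame with `locus_id` and `snp_pos`
#'   (defaults: column names, position 1).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, loci = NULL) {
  check_genotype_codes(geno)
  ids <- colnames(geno) %||% sprintf("L%05d", seq_len(ncol(geno)))
  pos <- rep(1L, ncol(geno))
  if (!is.null(loci)) {
    i <- match(ids, loci$locus_id)
    pos_ok <- !is.na(i) & !is.na(loci$snp_pos[i])
    pos[pos_ok] <- loci$snp_pos[i][pos_ok]
  }
  inds <- rownames(geno) %||% sprintf("ind_%04d", seq_len(nrow(geno)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hybridpanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", inds), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(ids[j], pos[j], ids[j], "A", "C", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype matrix as the TSV dialect
#'
#' Individuals as rows, loci as columns, codes 0/1/2, missing as `NA`.
#'
#' @inheritParams write_vcf
#' @export
write_genotypes_tsv <- function(geno, path) {
  check_genotype_codes(geno)
  d <- as.data.frame(geno)
  write.table(d, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write the locus-metadata sidecar
#'
#' Tab-separated table with columns `locus_id`, `tag_length`, `snp_pos`.
#'
#' @param loci locus data frame (e.g. `panel$loci`).
#' @param path output file.
#' @export
write_locus_meta <- function(loci, path) {
  write.table(loci[, c("locus_id", "tag_length", "snp_pos")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export genotypes in NEWHYBRIDS format
#'
#' Writes the two-column-per-locus lumped-genotype format accepted by the
#' original NEWHYBRIDS program (alleles coded 1/2, missing 0), with
#' reference individuals (rows of `ref_panel`) carrying `z0` / `z1`
#' known-origin flags, for cross-validation against that program. The
#' pipeline itself never shells out to NEWHYBRIDS.
#'
#' @param geno test individuals x loci genotype matrix.
#' @param path output file.
#' @param ref_panel optional `ref_panel` appended with z flags.
#' @export
write_newhybrids <- function(geno, path, ref_panel = NULL) {
  check_genotype_codes(geno)
  lump <- function(g) {
    out <- rep("0", length(g))
    out[!is.na(g) & g == 0L] <- "11"
    out[!is.na(g) & g == 1L] <- "12"
    out[!is.na(g) & g == 2L] <- "22"
    out
  }
  rows <- character(0)
  n_total <- nrow(geno) + if (is.null(ref_panel)) 0L else nrow(ref_panel$geno)
  lines <- c(paste("NumIndivs", n_total),
             paste("NumLoci", ncol(geno)),
             "Digits 1",
             "Format Lumped",
             paste(c("LocusNames", colnames(geno)), collapse = " "))
  idx <- 1L
  for (i in seq_len(nrow(geno))) {
    rows <- c(rows, paste(c(idx, lump(geno[i, ])), collapse = " "))
    idx <- idx + 1L
  }
  if (!is.null(ref_panel)) {
    zflag <- ifelse(ref_panel$pop == "pop0", "z0", "z1")
    for (i in seq_len(nrow(ref_panel$geno))) {
      rows <- c(rows, paste(c(idx, zflag[i], lump(ref_panel$geno[i, ])),
                            collapse = " "))
      idx <- idx + 1L
    }
  }
  writeLines(c(lines, rows), path)
  invisible(path)
}
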