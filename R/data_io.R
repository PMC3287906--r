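#' Genotype matrix container
#'
#' Holds raw genotype codes (0/1/2 copies of the counted allele, \code{NA}
#' for missing) together with subject identifiers and the SNP map that
#' establishes adjacency order. Columns are sorted by (chromosome,
#' position); adjacency (j, j+1) is only meaningful within a chromosome.
#'
#' @param codes n x p integer/numeric matrix with values in \{0, 1, 2\} or
#'   \code{NA}.
#' @param subjects length-n subject identifiers.
#' @param snps data frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (one row per SNP, matching \code{codes} columns).
#' @param metadata free-form list (e.g. the allele-counting convention).
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(codes, subjects = NULL, snps = NULL,
                            metadata = list()) {
  codes <- as.matrix(codes)
  n <- nrow(codes); p <- ncol(codes)
  if (n < 2 || p < 1)
    stop("genotype matrix needs n >= 2 subjects and p >= 1 SNPs",
         call. = FALSE)
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or missing; found ",
         paste(unique(codes[bad]), collapse = ", "), call. = FALSE)
  if (is.null(subjects)) subjects <- paste0("S", seq_len(n))
  if (anyDuplicated(subjects))
    stop("duplicate subject identifiers in genotype matrix", call. = FALSE)
  if (is.null(snps)) {
    ids <- colnames(codes)
    if (is.null(ids)) ids <- paste0("snp", seq_len(p))
    snps <- data.frame(id = ids, chrom = rep(1L, p), pos = seq_len(p),
                       stringsAsFactors = FALSE)
  }
  snps <- as.data.frame(snps)
  stopifnot(all(c("id", "chrom", "pos") %in% names(snps)),
            nrow(snps) == p)
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  codes <- codes[, ord, drop = FALSE]
  colnames(codes) <- snps$id
  rownames(codes) <- subjects
  structure(list(codes = codes, subjects = as.character(subjects),
                 snps = snps, metadata = metadata),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$codes), "subjects x", ncol(x$codes),
      "SNPs;", sum(is.na(x$codes)), "missing cells\n")
  invisible(x)
}

#' Read a genotype matrix from VCF, PLINK text, or TSV
#'
#' @param path input file. For \code{plink_text}, the \code{.ped} file (the
#'   matching \code{.map} is found by extension substitution) or the common
#'   prefix.
#' @param format one of \code{"vcf"}, \code{"plink_text"}, \code{"tsv"};
#'   guessed from the extension when missing.
#' @param map optional SNP map data frame (\code{id}, \code{chrom},
#'   \code{pos}) for TSV inputs, which carry no positional information.
#' @param ref_alleles for PLINK text: named character vector giving the
#'   counted (reference) allele per SNP id; unnamed SNPs count the
#'   lexicographically later of the two observed alleles. The SMCP model is
#'   invariant to this choice; the convention used is recorded in
#'   \code{metadata$allele_convention}.
#' @return a \code{\link{genotype_matrix}}. Codes count copies of the ALT
#'   allele (VCF) or the counted allele (PLINK); missing genotypes are
#'   \code{NA}. VCF multiallelic sites are skipped with a warning.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "plink_text"),
                           map = NULL, ref_alleles = NULL) {
  if (!missing(format)) format <- match.arg(format)
  else {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vcf = "vcf", ped = "plink_text", map = "plink_text",
                     "tsv")
  }
  if (format == "plink_text") return(read_plink_text(path, ref_alleles))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         tsv = read_genotypes_tsv(path, map),
         vcf = read_genotypes_vcf(path))
}

read_genotypes_tsv <- function(path, map = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("TSV genotype file needs a subject column plus ",
                          "at least one SNP column", call. = FALSE)
  subjects <- as.character(tab[[1]])
  codes <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(codes) <- "double"
  if (ncol(codes) == 0) stop("no usable SNPs in ", path, call. = FALSE)
  genotype_matrix(codes, subjects, snps = map,
                  metadata = list(source = path, format = "tsv",
                                  allele_convention = "codes as stored"))
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi))
    warning(sum(multi), " multiallelic site(s) skipped", call. = FALSE)
  keep <- !multi
  if (!any(keep)) stop("no usable biallelic SNPs in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # count ALT alleles in the GT string; any missing allele -> NA
  count_alt <- function(g) {
    if (is.na(g) || grepl("\\.", g)) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  }
  codes <- t(apply(gt, c(1, 2), count_alt))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  snps <- data.frame(id = ids, chrom = fix$CHROM,
                     pos = as.numeric(fix$POS), stringsAsFactors = FALSE)
  genotype_matrix(codes, colnames(gt), snps,
                  metadata = list(source = path, format = "vcf",
                                  allele_convention = "ALT allele count"))
}

read_plink_text <- function(path, ref_alleles = NULL) {
  base <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(base, ".ped"); map_path <- paste0(base, ".map")
  for (f in c(ped_path, map_path))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(map) < 4)
    stop("malformed .map file (expected 4 columns): ", map_path,
         call. = FALSE)
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  p <- nrow(map)
  if (ncol(ped) != 6 + 2 * p)
    stop("line width of ", ped_path, " does not match ", p,
         " SNPs in .map", call. = FALSE)
  subjects <- ped[[2]]
  codes <- matrix(NA_real_, nrow(ped), p)
  counted <- character(p)
  for (j in seq_len(p)) {
    a1 <- ped[[6 + 2 * j - 1]]; a2 <- ped[[6 + 2 * j]]
    obs <- setdiff(unique(c(a1, a2)), "0")
    if (length(obs) > 2)
      stop("more than 2 alleles at SNP ", map$id[j], " in ", ped_path,
           call. = FALSE)
    ref <- if (!is.null(ref_alleles) && map$id[j] %in% names(ref_alleles))
      ref_alleles[[map$id[j]]]
    else if (length(obs)) sort(obs, decreasing = TRUE)[1] else "0"
    counted[j] <- ref
    miss <- a1 == "0" | a2 == "0"
    codes[, j] <- (a1 == ref) + (a2 == ref)
    codes[miss, j] <- NA_real_
  }
  snps <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                     stringsAsFactors = FALSE)
  genotype_matrix(codes, subjects, snps,
                  metadata = list(source = ped_path, format = "plink_text",
                                  allele_convention = "counted allele per SNP",
                                  counted_allele = setNames(counted, map$id)))
}

#' Write a genotype matrix to TSV or a minimal VCF
#'
#' The TSV dialect is the one \code{\link{read_genotypes}} reads: header row
#' of SNP ids, first column the subject id. The VCF writer emits a minimal
#' v4.2 file with GT-only genotypes (placeholder REF/ALT alleles A/C; codes
#' are ALT counts), round-trippable through \code{read_genotypes}.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @export
write_genotypes <- function(geno, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(subject = geno$subjects,
                      geno$codes, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    gt_of <- function(g) if (is.na(g)) "./." else
      c("0/0", "0/1", "1/1")[g + 1]
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", geno$subjects),
                     collapse = "\t"))
    for (j in seq_len(ncol(geno$codes))) {
      gts <- vapply(geno$codes[, j], gt_of, character(1))
      lines <- c(lines, paste(c(geno$snps$chrom[j], geno$snps$pos[j],
                                geno$snps$id[j], "A", "C", ".", "PASS",
                                ".", "GT", gts), collapse = "\t"))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phenotype table with expanded covariates
#'
#' @param subjects subject identifiers (unique).
#' @param trait numeric quantitative trait.
#' @param covariates data frame of covariates; character/factor columns are
#'   expanded to k-1 indicator columns against the lexicographically first
#'   level as reference.
#' @return object of class \code{phenotype_table} with all-numeric
#'   covariates.
#' @export
phenotype_table <- function(subjects, trait, covariates = NULL) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects))
    stop("duplicate subject identifiers in phenotype table", call. = FALSE)
  trait <- as.numeric(trait)
  stopifnot(length(trait) == length(subjects))
  cov <- expand_covariates(covariates, n = length(subjects))
  structure(list(subjects = subjects, trait = trait, covariates = cov),
            class = "phenotype_table")
}

expand_covariates <- function(covariates, n) {
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(data.frame(row.names = seq_len(n)))
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  out <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v) || is.logical(v)) {
      out[[nm]] <- as.numeric(v)
    } else {
      lev <- sort(unique(as.character(v)))       # lexicographic; first = ref
      for (l in lev[-1])
        out[[paste0(nm, "_", l)]] <- as.numeric(as.character(v) == l)
    }
  }
  as.data.frame(out, row.names = seq_len(n))
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited with a subject-id column (first column by default), a
#' trait column named \code{trait_col}, and any further columns treated as
#' covariates. Categorical covariates are expanded to k-1 indicators
#' (lexicographically first level as reference).
#'
#' @param path input file.
#' @param trait_col name of the trait column.
#' @param subject_col name of the subject-id column; default first column.
#' @return a \code{\link{phenotype_table}}.
#' @export
read_phenotypes <- function(path, trait_col = "trait",
                            subject_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(subject_col)) subject_col <- names(tab)[1]
  if (!trait_col %in% names(tab))
    stop("phenotype file has no trait column '", trait_col, "'",
         call. = FALSE)
  keep_trait <- !is.na(tab[[trait_col]])
  if (!all(keep_trait)) {
    message(sum(!keep_trait), " subject(s) with missing trait dropped")
    tab <- tab[keep_trait, , drop = FALSE]
  }
  covs <- tab[, setdiff(names(tab), c(subject_col, trait_col)),
              drop = FALSE]
  phenotype_table(tab[[subject_col]], tab[[trait_col]], covs)
}

#' Write an association report
#'
#' Emits a tab-delimited table with one row per SNP (columns: snp,
#' chromosome, position, gene, univariate estimate and p-value, SMCP
#' estimate and LOO p-value, LASSO estimate and LOO p-value; cells for SNPs
#' a model did not select are left empty) plus a JSON sidecar
#' (\code{<path>.meta.json}) with the full fit metadata: tuning values,
#' seeds, convergence flags.
#'
#' @param report an \code{association_report} (see
#'   \code{\link{association_report}}).
#' @param path output TSV path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "association_report"))
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  jsonlite::write_json(report$metadata, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Assemble an association report
#'
#' @param table data frame with columns \code{snp}, \code{chromosome},
#'   \code{position}, \code{gene}, \code{univariate_estimate},
#'   \code{univariate_p}, \code{smcp_estimate}, \code{smcp_loo_p},
#'   \code{lasso_estimate}, \code{lasso_loo_p} (missing ones are added as
#'   \code{NA}).
#' @param metadata list of fit metadata (selected tau values, eta, gamma,
#'   seeds, convergence flags).
#' @return object of class \code{association_report}.
#' @export
association_report <- function(table, metadata = list()) {
  cols <- c("snp", "chromosome", "position", "gene",
            "univariate_estimate", "univariate_p",
            "smcp_estimate", "smcp_loo_p",
            "lasso_estimate", "lasso_loo_p")
  for (cl in setdiff(cols, names(table))) table[[cl]] <- NA
  table <- table[, cols, drop = FALSE]
  if (nrow(table)) {
    pcols <- c("univariate_p", "smcp_loo_p", "lasso_loo_p")
    for (cl in pcols) {
      pv <- table[[cl]]
      if (any(!is.na(pv) & (pv < 0 | pv > 1)))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(table = table, metadata = metadata),
            class = "association_report")
}
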