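#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (optionally gzipped), keeps biallelic SNPs only and
#' encodes unphased or phased genotypes as alternate-allele dosages.  Phase
#' separators (`|`) are accepted but phase information is ignored.  Missing
#' genotypes (`./.` or `.`) are masked.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param ploidy expected ploidy of the calls; a haploid read of diploid calls
#'   is an error rather than a silent conversion.
#' @param min_call_rate,min_maf site filters applied after reading, see
#'   [filter_sites()].
#' @param verbose log the number of non-biallelic sites dropped.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, ploidy = c("diploid", "haploid"),
                     min_call_rate = 0.9, min_maf = 0.01, verbose = FALSE) {
  ploidy <- match.arg(ploidy)
  if (!file.exists(path)) abort(sprintf("cannot read VCF: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  biall <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  if (verbose && any(!biall))
    message(sprintf("read_vcf: dropped %d non-biallelic/non-SNP site(s)", sum(!biall)))
  if (!any(biall)) abort("no usable biallelic SNPs in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[biall, , drop = FALSE]
  fix <- fix[biall, , drop = FALSE]
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  is_dip <- grepl("/", gt_clean, fixed = TRUE)
  n_alleles <- ifelse(is.na(gt_clean), NA, ifelse(is_dip, 2L, 1L))
  obs <- unique(n_alleles[!is.na(n_alleles)])
  if (length(obs) > 1) abort("mixed ploidy across genotype calls")
  if (ploidy == "haploid" && any(obs == 2L))
    abort("file contains diploid calls; refusing haploid read (no silent halving)")
  if (ploidy == "diploid" && any(obs == 1L))
    abort("file contains haploid calls; use ploidy = 'haploid'")
  dos <- if (ploidy == "diploid") {
    (gt_clean == "0/1" | gt_clean == "1/0") + 2L * (gt_clean == "1/1")
  } else {
    (gt_clean == "1") * 1L
  }
  dos[is.na(gt_clean) | gt_clean %in% c("./.", ".")] <- NA_integer_
  cm <- rep(NA_real_, nrow(fix))
  info <- fix[, "INFO"]
  has_cm <- !is.na(info) & grepl("cM=", info, fixed = TRUE)
  cm[has_cm] <- as.numeric(sub(".*cM=([0-9eE.+-]+).*", "\\1", info[has_cm]))
  sites <- tibble(
    chrom = fix[, "CHROM"],
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    position_bp = as.integer(fix[, "POS"]),
    position_cM = cm,
    ref = fix[, "REF"], alt = fix[, "ALT"])
  g <- genotype_matrix(t(dos), sites, ploidy)
  filter_sites(g, min_call_rate, min_maf, verbose = verbose)
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT fields (`0/0`, `0/1`, `1/1` for diploids;
#' `0`/`1` for haploids) and, when a genetic map is present, a `cM=` entry in
#' INFO so that a write-then-read round trip preserves coordinates.
#'
#' @param g a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  d <- g$dosages
  n <- nrow(d)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=cM,Number=1,Type=Float,Description=\"Genetic position in centiMorgans\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("ind", seq_len(n))), collapse = "\t"))
  code <- if (g$ploidy == "diploid") c("0/0", "0/1", "1/1") else c("0", "1")
  gt <- matrix(code[d + 1L], nrow = n)
  gt[is.na(d)] <- if (g$ploidy == "diploid") "./." else "."
  info <- ifelse(is.na(g$sites$position_cM), ".",
                 sprintf("cM=%.8g", g$sites$position_cM))
  body <- paste(g$sites$chrom, g$sites$position_bp, g$sites$id, g$sites$ref,
                g$sites$alt, ".", "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_map_file <- function(map) {
  m <- data.table::fread(map, header = FALSE, data.table = FALSE)
  if (ncol(m) < 4) abort("MAP file needs 4 columns: chrom, id, cM, bp")
  names(m)[1:4] <- c("chrom", "id", "cM", "bp")
  m$chrom <- as.character(m$chrom)
  m
}

#' Read genotypes from PLINK PED+MAP or TPED(+TFAM) files
#'
#' `.ped` files carry one individual per row with two allele columns per site
#' and need an accompanying `.map` file for site locations; `.tped` files carry
#' one site per row with map columns inline.  Alleles `0 0` are missing.  The
#' minor allele at each site becomes the counted (alt) allele.  A cM column
#' that is all zero is treated as "no genetic map".
#'
#' @param path path to a `.ped` or `.tped` file.
#' @param map path to the `.map` file (required for PED, ignored for TPED).
#' @param ploidy,min_call_rate,min_maf,verbose as in [read_vcf()].
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(path, map = NULL, ploidy = c("diploid", "haploid"),
                       min_call_rate = 0.9, min_maf = 0.01, verbose = FALSE) {
  ploidy <- match.arg(ploidy)
  if (!file.exists(path)) abort(sprintf("cannot read file: %s", path))
  tped <- grepl("\\.tped$", path, ignore.case = TRUE)
  if (tped) {
    x <- data.table::fread(path, header = FALSE, data.table = FALSE,
                           colClasses = "character")
    mp <- data.frame(chrom = x[[1]], id = x[[2]], cM = as.numeric(x[[3]]),
                     bp = as.integer(x[[4]]))
    al <- as.matrix(x[, -(1:4), drop = FALSE])  # sites x (2*n or n)
  } else {
    if (is.null(map)) abort("PED input requires a MAP file")
    mp <- read_map_file(map)
    x <- data.table::fread(path, header = FALSE, data.table = FALSE,
                           colClasses = "character")
    if (ncol(x) < 7) abort("malformed PED file")
    al <- t(as.matrix(x[, -(1:6), drop = FALSE]))  # allele columns x ind -> sites*2 x n
  }
  ncol_per_site <- if (ploidy == "diploid") 2L else 1L
  n_sites_al <- (if (tped) ncol(al) else nrow(al)) / ncol_per_site
  if (tped) n_sites_al <- nrow(al)
  if (!tped && n_sites_al != nrow(mp))
    abort(sprintf("PED implies %s sites but MAP has %d rows", n_sites_al, nrow(mp)))
  if (tped) {
    n_ind <- ncol(al) / ncol_per_site
    if (n_ind != floor(n_ind)) abort("TPED allele columns not a multiple of ploidy")
  }
  # assemble allele pair matrices: a1, a2 are sites x individuals
  if (tped) {
    if (ploidy == "diploid") {
      a1 <- al[, seq(1, ncol(al), 2), drop = FALSE]
      a2 <- al[, seq(2, ncol(al), 2), drop = FALSE]
    } else a1 <- a2 <- al
  } else {
    if (ploidy == "diploid") {
      a1 <- al[seq(1, nrow(al), 2), , drop = FALSE]
      a2 <- al[seq(2, nrow(al), 2), , drop = FALSE]
    } else a1 <- a2 <- al
  }
  miss <- a1 == "0" | a2 == "0"
  dos <- matrix(NA_integer_, nrow(a1), ncol(a1))
  ref <- alt <- character(nrow(a1))
  for (j in seq_len(nrow(a1))) {
    aa <- c(a1[j, !miss[j, ]], a2[j, !miss[j, ]])
    lv <- sort(unique(aa))
    if (length(lv) > 2) abort(sprintf("site %s has >2 alleles", mp$id[j]))
    if (length(lv) == 1) lv <- c(lv, NA)
    cnt <- table(factor(aa, levels = lv[!is.na(lv)]))
    # count the minor allele
    alt_a <- if (length(cnt) == 2 && cnt[2] <= cnt[1]) lv[2] else lv[1]
    ref_a <- setdiff(lv[!is.na(lv)], alt_a)
    if (length(ref_a) == 0) ref_a <- "N"
    ref[j] <- ref_a[1]; alt[j] <- alt_a
    dj <- (a1[j, ] == alt_a) + (a2[j, ] == alt_a)
    if (ploidy == "haploid") dj <- (a1[j, ] == alt_a) * 1L
    dj[miss[j, ]] <- NA_integer_
    dos[j, ] <- as.integer(dj)
  }
  cm <- mp$cM
  if (all(is.na(cm)) || all(cm == 0)) cm <- rep(NA_real_, nrow(mp))
  sites <- tibble(chrom = as.character(mp$chrom), id = mp$id,
                  position_bp = as.integer(mp$bp), position_cM = cm,
                  ref = ref, alt = alt)
  g <- genotype_matrix(t(dos), sites, ploidy)
  filter_sites(g, min_call_rate, min_maf, verbose = verbose)
}

#' Write a genotype matrix as TPED + TFAM
#'
#' Alleles are written as `ref`/`alt` labels; missing genotypes as `0 0`.
#' Genetic positions go to the TPED cM column (0 when absent).
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix; writes `<prefix>.tped` and `<prefix>.tfam`.
#' @return The TPED path, invisibly.
#' @export
write_tped <- function(g, prefix) {
  d <- g$dosages
  n <- nrow(d)
  cm <- ifelse(is.na(g$sites$position_cM), 0, g$sites$position_cM)
  lines <- character(ncol(d))
  for (j in seq_len(ncol(d))) {
    r <- g$sites$ref[j]; a <- g$sites$alt[j]
    if (g$ploidy == "diploid") {
      al <- rbind(c(r, r), c(r, a), c(a, a))[d[, j] + 1L, , drop = FALSE]
      al[is.na(d[, j]), ] <- "0"
    } else {
      al <- cbind(c(r, a)[d[, j] + 1L], c(r, a)[d[, j] + 1L])
      al[is.na(d[, j]), ] <- "0"
    }
    lines[j] <- paste(g$sites$chrom[j], g$sites$id[j], format(cm[j], digits = 8),
                      g$sites$position_bp[j],
                      paste(t(al), collapse = " "))
  }
  writeLines(lines, paste0(prefix, ".tped"))
  writeLines(paste("FAM", paste0("ind", seq_len(n)), 0, 0, 0, -9), paste0(prefix, ".tfam"))
  invisible(paste0(prefix, ".tped"))
}
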