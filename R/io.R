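#' Read a long-format phenotype table
#'
#' Expects delimited text with a header containing at least `subject`,
#' `time` and `y` columns (one row per observation); any further columns are
#' kept as candidate covariates. Wide per-subject layouts are rejected: the
#' long format is the canonical interchange because subjects may have
#' different numbers of measurements.
#'
#' @param path File path.
#' @param sep Field separator (default: any whitespace/tab).
#' @return Validated data frame.
#' @export
read_phenotypes <- function(path, sep = "") {
  ph <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject", "time", "y")
  if (!all(need %in% names(ph))) {
    stop("phenotype file must have columns subject, time, y (long format, ",
         "one row per observation)")
  }
  if (!is.numeric(ph$y)) stop("non-numeric trait values in column 'y'")
  if (!is.numeric(ph$time)) stop("non-numeric values in column 'time'")
  dup <- duplicated(ph[c("subject", "time")])
  if (any(dup)) {
    stop("duplicate (subject, time) rows at lines: ",
         paste(utils::head(which(dup) + 1L, 5), collapse = ", "))
  }
  ph
}

#' Read a genotype matrix from delimited text or VCF
#'
#' Delimited text: rows are individuals, columns are SNPs, with a header of
#' SNP ids. Files ending in `.vcf` / `.vcf.gz` are parsed with the `vcfR`
#' package and converted to additive dosages (count of alternate alleles);
#' the returned matrix is individuals x sites.
#'
#' @param path File path.
#' @param sep Field separator for delimited text.
#' @return Numeric matrix (individuals x SNPs) with SNP ids as column names.
#' @export
read_genotypes <- function(path, sep = "") {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dosage <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
    return(t(dosage)) # individuals x sites
  }
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

# write-temp-then-rename so readers never see a partial file
atomic_write <- function(write_fun, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file onto ", path)
  invisible(path)
}

#' Write / read a genome profile table
#'
#' Tab-delimited text with one row per SNP ([genome_profile()] columns).
#' Writes are atomic (write to a temporary file, then rename).
#'
#' @param profile A [genome_profile()] data frame.
#' @param path Output path.
#' @return `path`, invisibly (`write_profile`); the profile data frame
#'   (`read_profile`).
#' @export
write_profile <- function(profile, path) {
  atomic_write(function(tmp) {
    utils::write.table(profile, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write simulated study inputs to delimited files
#'
#' Writes the genotype matrix, the long phenotype table and a plain-text
#' truth record (causal SNPs, scale constant, variance components) into a
#' directory, so a simulated study can be rerun through the file-based
#' interface.
#'
#' @param sim A [sim_study()] object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "gblmm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  G <- sim$genotypes
  colnames(G) <- paste0("snp", seq_len(ncol(G)))
  atomic_write(function(tmp) utils::write.table(G, tmp, sep = "\t",
    quote = FALSE, row.names = FALSE), file.path(dir, "genotypes.tsv"))
  atomic_write(function(tmp) utils::write.table(sim$phenotypes, tmp, sep = "\t",
    quote = FALSE, row.names = FALSE), file.path(dir, "phenotypes.tsv"))
  tr <- sim$truth
  atomic_write(function(tmp) writeLines(c(
    paste("setup", tr$setup),
    paste("causal", paste(tr$causal, collapse = ",")),
    paste("c_g", format(tr$c_g, digits = 12)),
    paste("delta", paste(tr$delta, collapse = ",")),
    paste("psi", paste(tr$psi, collapse = ",")),
    paste("sigma2", tr$sigma2),
    paste("h2_target", tr$h2_target),
    paste("h2_realized", format(tr$h2_realized, digits = 8)),
    paste("seed", if (is.null(tr$seed)) NA else tr$seed)
  ), tmp), file.path(dir, "truth.txt"))
  invisible(dir)
}
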