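# Readers and writers for the formats the toolkit touches: variant
# panels as VCF, consensus reads as FASTQ, profiles / signatures /
# observations as TSV, and run configuration as YAML. Internal
# coordinates are 0-based half-open; the VCF boundary converts to and
# from VCF's 1-based positions.

#' Read a tumor-informed SNV panel from a VCF file
#'
#' SNV records (single-base REF and ALT) are loaded; other records are
#' skipped with a message. The VAF is taken from an INFO key (default
#' `AF`); tumor purity is read from a `##tumor_purity=` header line
#' unless supplied explicitly. VCF 1-based positions are converted to
#' internal 0-based coordinates.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @param vaf_key INFO key holding the variant allele frequency.
#' @param purity Tumor purity; overrides any header value.
#' @return A `"variant_panel"`.
#' @export
read_variant_panel_vcf <- function(path, vaf_key = "AF", purity = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  vaf <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = vaf_key))
  )
  stop_if(all(is.na(vaf)),
          sprintf("VAF key `%s` absent from INFO", vaf_key))
  is_snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% BASES & fix$ALT %in% BASES
  if (any(!is_snv))
    message(sum(!is_snv), " non-SNV record(s) skipped")
  stop_if(anyNA(vaf[is_snv]),
          sprintf("SNV record without INFO/%s value", vaf_key))
  if (is.null(purity)) {
    meta <- grep("^##tumor_purity=", vcf@meta, value = TRUE)
    purity <- if (length(meta)) as.numeric(sub("^##tumor_purity=", "", meta[1]))
              else 1
  }
  new_variant_panel(
    data.frame(chrom = fix$CHROM[is_snv],
               pos = as.integer(fix$POS[is_snv]) - 1L,
               ref = fix$REF[is_snv], alt = fix$ALT[is_snv],
               vaf = vaf[is_snv], row.names = NULL),
    purity
  )
}

#' Write a variant panel to a (gzipped) VCF file
#'
#' Positions are written 1-based; VAF goes to `INFO/AF` and purity to a
#' `##tumor_purity=` header line.
#'
#' @param panel A `"variant_panel"`.
#' @param path Output path (vcfR writes gzip-compressed VCF text).
#' @return `path`, invisibly.
#' @export
write_variant_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "variant_panel"))
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##tumor_purity=%.6g", attr(panel, "purity")),
            "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency in the tumor biopsy\">")
  fix <- cbind(
    CHROM = panel$chrom, POS = as.character(panel$pos + 1L),
    ID = ".", REF = panel$ref, ALT = panel$alt, QUAL = ".",
    FILTER = "PASS", INFO = sprintf("AF=%.6g", panel$vaf)
  )
  vcf <- new("vcfR", meta = meta, fix = fix,
             gt = matrix(character(0), nrow = nrow(panel), ncol = 0))
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

# Consensus-read FASTQ: metadata rides in the read name as
# id|chrom|start|end|n_repeats|timestamp; qualities are Phred+33.

#' Write consensus reads to FASTQ
#'
#' @param reads List of `"consensus_read"` objects.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  if (length(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  ids <- vapply(reads, function(r) sprintf(
    "%s|%s|%d|%d|%d|%.6f", r$template_id, r$coords$chrom,
    as.integer(r$coords$start), as.integer(r$coords$end),
    r$n_repeats, r$timestamp), "")
  seqs <- Biostrings::DNAStringSet(vapply(reads, `[[`, "", "seq"))
  names(seqs) <- ids
  quals <- Biostrings::PhredQuality(vapply(reads, function(r)
    intToUtf8(r$qual + 33L), ""))
  # Biostrings warns about dropping (empty) metadata columns here
  qs <- suppressWarnings(
    Biostrings::QualityScaledDNAStringSet(seqs, quals))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read consensus reads from FASTQ written by [write_reads_fastq()]
#'
#' @param path FASTQ path.
#' @return List of `"consensus_read"` objects.
#' @export
read_reads_fastq <- function(path) {
  if (file.size(path) == 0) return(list())
  # same benign metadata-column warning as on the write side
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  lapply(seq_along(qs), function(i) {
    parts <- strsplit(names(qs)[i], "|", fixed = TRUE)[[1]]
    stop_if(length(parts) != 6,
            sprintf("malformed read name at record %d", i))
    structure(list(
      template_id = parts[1], seq = as.character(qs[[i]]),
      qual = as.integer(utf8ToInt(as.character(
        Biostrings::quality(qs)[[i]])) - 33L),
      n_repeats = as.integer(parts[5]),
      coords = list(chrom = parts[2], start = as.integer(parts[3]),
                    end = as.integer(parts[4])),
      timestamp = as.numeric(parts[6])
    ), class = "consensus_read")
  })
}

#' @rdname profile_tsv
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(length = as.integer(names(profile)),
               density = as.numeric(profile)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Fragment-length profile TSV I/O
#'
#' Two-column TSV (`length`, `density`) with a header line, UTF-8,
#' `.` decimal separator.
#'
#' @param profile A `"length_profile"`.
#' @param path TSV path.
#' @return The profile (reader) or `path` invisibly (writer).
#' @name profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stop_if(!all(c("length", "density") %in% names(df)),
          "profile TSV must have `length` and `density` columns")
  structure(stats::setNames(df$density, df$length),
            class = "length_profile")
}

#' @rdname signatures_tsv
#' @export
write_signatures_tsv <- function(signatures, path) {
  stopifnot(inherits(signatures, "signature_matrix"))
  utils::write.table(
    data.frame(length = as.integer(colnames(signatures)),
               signature_1 = signatures[1, ],
               signature_2 = signatures[2, ]),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Signature-matrix TSV I/O
#'
#' Three-column TSV (`length`, `signature_1`, `signature_2`) carrying
#' the two fixed fragment-length signatures; the override path for
#' literature-derived signatures.
#'
#' @param signatures A `"signature_matrix"`.
#' @param path TSV path.
#' @return The signature matrix (reader) or `path` invisibly (writer).
#' @name signatures_tsv
#' @export
read_signatures_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stop_if(!all(c("length", "signature_1", "signature_2") %in% names(df)),
          "signature TSV must have length, signature_1, signature_2 columns")
  signature_matrix(df$signature_1, df$signature_2, df$length,
                   provenance = path)
}

#' @rdname observations_tsv
#' @export
write_observations_tsv <- function(observations, path) {
  stopifnot(inherits(observations, "allele_obs"))
  fp <- attr(observations, "panel_fingerprint")
  header <- sprintf("# panel_fingerprint=%d,%.0f run_minutes=%.6g",
                    fp[1], fp[2], attr(observations, "run_minutes"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(observations), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allele-observation TSV I/O
#'
#' TSV with columns `site_index`, `call`, `timestamp` (minutes from run
#' start) and a comment header carrying the panel fingerprint and run
#' duration.
#'
#' @param observations An `"allele_obs"` object.
#' @param path TSV path.
#' @return The observations (reader) or `path` invisibly (writer).
#' @name observations_tsv
#' @export
read_observations_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  stop_if(!grepl("^# panel_fingerprint=", first),
          "malformed observations TSV at line 1: missing fingerprint header")
  fp <- as.numeric(strsplit(sub("^# panel_fingerprint=([^ ]+).*", "\\1",
                                first), ",")[[1]])
  run_min <- as.numeric(sub(".*run_minutes=", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  stop_if(!all(df$call %in% c("REF", "MUT", "ERR")),
          "observations TSV contains calls outside {REF, MUT, ERR}")
  attr(df, "panel_fingerprint") <- fp
  attr(df, "run_minutes") <- run_min
  class(df) <- c("allele_obs", "data.frame")
  df
}

#' Run-configuration YAML I/O
#'
#' A run configuration is a named list (seeds, generator parameters,
#' grid and trial sizes, platform presets, file paths) that round-trips
#' losslessly through YAML.
#'
#' @param config Named list.
#' @param path YAML path.
#' @return The configuration list (reader) or `path` invisibly (writer).
#' @name run_config
#' @export
write_run_config <- function(config, path) {
  stop_if(is.null(names(config)) || any(names(config) == ""),
          "config entries must be named")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
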