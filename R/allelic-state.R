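# Allele specificity of 3C ligation products from SNP signals, and
# imprinting-control-region (ICR) methylation QC.
#
# A ligation product carrying only one haplotype indicates a contact engaged
# on a single parental allele (monoallelic); both haplotypes indicate a
# biallelic contact. Parental origin is never assigned computationally: it is
# at most a user-supplied annotation, because origin can only be inferred
# indirectly.

#' Qualitative haplotype call from per-SNP allele presence
#'
#' Mirrors Sanger sequencing of a 3C product at heterozygous SNPs: if every
#' SNP shows a single allele (minor signal below `minor_presence` of the
#' major peak), the contact is monoallelic and the haplotype string
#' concatenates the observed alleles in genomic coordinate order; if any SNP
#' shows both alleles, the contact is biallelic. Homozygous samples are
#' uninformative.
#'
#' @param signals Tibble with columns `snp_id`, `allele_a`, `allele_b`,
#'   `signal_a`, `signal_b`, ordered by genomic coordinate.
#' @param heterozygous Logical: is the sample heterozygous at the tested
#'   SNPs? (`FALSE` forces an uninformative call.)
#' @param minor_presence Fraction of the major peak above which the minor
#'   allele counts as present (default 0.2).
#' @return One-row tibble: `classification` in monoallelic / biallelic /
#'   uninformative, `haplotype` (NA unless monoallelic).
#' @export
#' @examples
#' sig <- tibble::tibble(snp_id = c("rs59121562", "rs80047492"),
#'   allele_a = c("T", "T"), allele_b = c("A", "A"),
#'   signal_a = c(100, 95), signal_b = c(2, 0))
#' call_haplotype(sig)
call_haplotype <- function(signals, heterozygous = TRUE,
                           minor_presence = 0.2) {
  if (nrow(signals) < 1) stop("no SNP signals", call. = FALSE)
  if (any(signals$allele_a == signals$allele_b)) {
    stop("allele_a and allele_b must differ", call. = FALSE)
  }
  if (any(signals$signal_a == 0 & signals$signal_b == 0)) {
    stop("all-zero signals at SNP ",
         signals$snp_id[signals$signal_a == 0 & signals$signal_b == 0][1],
         call. = FALSE)
  }
  if (!heterozygous) {
    return(tibble::tibble(classification = "uninformative",
                          haplotype = NA_character_))
  }
  major <- pmax(signals$signal_a, signals$signal_b)
  minor <- pmin(signals$signal_a, signals$signal_b)
  both_present <- minor >= minor_presence * major
  if (any(both_present)) {
    return(tibble::tibble(classification = "biallelic",
                          haplotype = NA_character_))
  }
  hap <- paste(ifelse(signals$signal_a >= signals$signal_b,
                      signals$allele_a, signals$allele_b), collapse = "")
  tibble::tibble(classification = "monoallelic", haplotype = hap)
}

#' Quantitative allele fraction and mono/biallelic classification
#'
#' For mass-spectrometry style quantitative SNP readouts: the fraction of
#' allele A is `signal_a / (signal_a + signal_b)`; a contact is monoallelic
#' when the major-allele fraction reaches `theta`, biallelic otherwise. The
#' call is invariant to common scaling of the two signals.
#'
#' @param signal_a,signal_b Non-negative signal intensities (vectorized).
#' @param theta Monoallelic threshold on the major-allele fraction
#'   (default 0.8).
#' @return Tibble: `fraction_a`, `major_fraction`, `classification`.
#' @export
#' @examples
#' quantify_allele_fraction(900, 100)
quantify_allele_fraction <- function(signal_a, signal_b, theta = 0.8) {
  if (any(signal_a < 0) || any(signal_b < 0)) {
    stop("signals must be non-negative", call. = FALSE)
  }
  tot <- signal_a + signal_b
  if (any(tot == 0)) stop("both signals zero", call. = FALSE)
  fa <- signal_a / tot
  mf <- pmax(fa, 1 - fa)
  tibble::tibble(
    fraction_a = fa,
    major_fraction = mf,
    classification = ifelse(mf >= theta, "monoallelic", "biallelic")
  )
}

#' Normal pyrosequencing methylation ranges for the two ICRs
#'
#' Reference ranges (percent methylation, inclusive bounds) used to classify
#' a sample as normally methylated.
#'
#' @param icr1 Length-2 numeric, normal range for ICR1 (default 40-52).
#' @param icr2 Length-2 numeric, normal range for ICR2 (default 39-50).
#' @return A list of class `methylation_ranges`.
#' @export
methylation_ranges <- function(icr1 = c(40, 52), icr2 = c(39, 50)) {
  stopifnot(length(icr1) == 2, length(icr2) == 2,
            icr1[1] < icr1[2], icr2[1] < icr2[2])
  structure(list(ICR1 = icr1, ICR2 = icr2), class = "methylation_ranges")
}

#' Classify ICR methylation level
#'
#' Below the normal range is hypomethylated, above is hypermethylated,
#' within (bounds inclusive) is normal. The partition of [0, 100] is total
#' and deterministic for each ICR.
#'
#' @param level Percent methylation in [0, 100] (vectorized).
#' @param icr `"ICR1"` or `"ICR2"` (vectorized, recycled).
#' @param ranges A [methylation_ranges()].
#' @return Character vector of statuses.
#' @export
#' @examples
#' classify_methylation(c(78, 16, 42), c("ICR1", "ICR2", "ICR1"))
classify_methylation <- function(level, icr, ranges = methylation_ranges()) {
  if (any(level < 0 | level > 100)) {
    stop("methylation level must lie in [0, 100]", call. = FALSE)
  }
  if (any(!icr %in% c("ICR1", "ICR2"))) {
    stop("icr must be ICR1 or ICR2", call. = FALSE)
  }
  n <- max(length(level), length(icr))
  level <- rep_len(level, n); icr <- rep_len(icr, n)
  vapply(seq_len(n), function(i) {
    rng <- ranges[[icr[i]]]
    if (level[i] < rng[1]) "hypomethylated"
    else if (level[i] > rng[2]) "hypermethylated"
    else "normal"
  }, "")
}

#' Infer molecular subtype from the two ICR statuses
#'
#' Combines the ICR1 and ICR2 methylation statuses into the molecular
#' subtype labels used for 11p15.5 imprinting disorders: ICR1 gain of
#' methylation alone is BWS-ICR1-like, ICR2 loss alone BWS-ICR2-like, gain
#' at ICR1 with loss at ICR2 is the paternal-UPD signature, ICR1 loss alone
#' SRS-ICR1-like.
#'
#' @param icr1_status,icr2_status Statuses from [classify_methylation()]
#'   (vectorized, recycled).
#' @return Character vector of subtype labels.
#' @export
#' @examples
#' infer_subtype("hypermethylated", "normal")
infer_subtype <- function(icr1_status, icr2_status) {
  valid <- c("normal", "hypomethylated", "hypermethylated")
  if (any(!icr1_status %in% valid) || any(!icr2_status %in% valid)) {
    stop("invalid methylation status", call. = FALSE)
  }
  n <- max(length(icr1_status), length(icr2_status))
  s1 <- rep_len(icr1_status, n); s2 <- rep_len(icr2_status, n)
  key <- paste(s1, s2)
  out <- rep("unclassified", n)
  out[key == "normal normal"] <- "normal"
  out[key == "hypermethylated normal"] <- "BWS-ICR1-like"
  out[key == "normal hypomethylated"] <- "BWS-ICR2-like"
  out[key == "hypermethylated hypomethylated"] <- "BWS-UPD-like"
  out[key == "hypomethylated normal"] <- "SRS-ICR1-like"
  out
}

#' Methylation QC over a sample table
#'
#' @param meth Tibble with columns `sample`, `icr`, `level_percent`.
#' @param ranges A [methylation_ranges()].
#' @return Per-row status plus a per-sample `subtype` column when both ICRs
#'   are present.
#' @export
classify_methylation_table <- function(meth, ranges = methylation_ranges()) {
  out <- tibble::as_tibble(meth)
  out$status <- classify_methylation(out$level_percent, out$icr, ranges)
  wide <- tidyr::pivot_wider(out[, c("sample", "icr", "status")],
                             names_from = "icr", values_from = "status")
  if (all(c("ICR1", "ICR2") %in% names(wide))) {
    wide$subtype <- infer_subtype(wide$ICR1, wide$ICR2)
    out <- dplyr::left_join(out, wide[, c("sample", "subtype")],
                            by = "sample")
  }
  out
}

#' Read SNP-signal and methylation tables
#'
#' `read_snp_signals()` expects columns `interaction`, `snp_id`, `allele_a`,
#' `allele_b`, `signal_a`, `signal_b`; `read_methylation()` expects `sample`,
#' `icr`, `level_percent`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_snp_signals <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_snp_signals
#' @export
read_methylation <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
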