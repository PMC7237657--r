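# Genomic landscape of the locus: annotated elements, restriction enzymes,
# in-silico digestion, and the fragment axis used by the 3C quantification.
#
# Coordinates are 0-based half-open (BED convention) everywhere in memory and
# on disk; 1-based closed coordinates appear only in human-readable reports.

ELEMENT_KINDS <- c("gene", "ICR", "CTCF_cluster", "enhancer",
                   "anchor_primer", "test_primer")

#' Built-in restriction enzyme table
#'
#' Recognition motifs and top-strand cut offsets for the enzymes used in the
#' 3C protocol. Both motifs are palindromic, so top-strand scanning of the
#' motif finds every site.
#'
#' @param name Optional enzyme name; when given, the single matching row is
#'   returned (error if unknown).
#' @return A tibble with columns `name`, `recognition`, `cut_offset`.
#' @export
#' @examples
#' restriction_enzymes()
#' restriction_enzymes("BglII")
restriction_enzymes <- function(name = NULL) {
  tbl <- tibble::tibble(
    name = c("BglII", "BamHI"),
    recognition = c("AGATCT", "GGATCC"),
    cut_offset = c(1L, 1L)
  )
  if (is.null(name)) return(tbl)
  hit <- tbl[tbl$name == name, ]
  if (nrow(hit) == 0) {
    stop("unknown enzyme '", name, "'; available: ",
         paste(tbl$name, collapse = ", "), call. = FALSE)
  }
  hit
}

validate_enzyme <- function(enzyme) {
  stopifnot(is.data.frame(enzyme), nrow(enzyme) == 1)
  rec <- toupper(enzyme$recognition)
  if (!grepl("^[ACGT]+$", rec)) {
    stop("enzyme recognition motif must contain only A/C/G/T", call. = FALSE)
  }
  off <- enzyme$cut_offset
  if (off < 0 || off > nchar(rec)) {
    stop("cut_offset must lie within the recognition motif", call. = FALSE)
  }
  invisible(enzyme)
}

#' Read an annotated-element table (BED-like 5-column TSV)
#'
#' Columns: chrom, start, end, name, kind. Coordinates are 0-based half-open.
#' Kinds are restricted to gene, ICR, CTCF_cluster, enhancer, anchor_primer,
#' test_primer.
#'
#' @param path Path to the TSV (no header).
#' @return A tibble of elements in coordinate order.
#' @export
read_elements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          kind = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 5)
  if (length(bad) > 0) {
    stop("malformed element line ", bad[1], ": expected 5 tab-separated ",
         "columns (chrom, start, end, name, kind)", call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2))),
    end   = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3))),
    name  = vapply(fields, `[[`, "", 4),
    kind  = vapply(fields, `[[`, "", 5)
  )
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad) > 0) {
    stop("malformed element line ", bad[1], ": non-numeric coordinates",
         call. = FALSE)
  }
  bad <- which(out$start < 0 | out$start >= out$end)
  if (length(bad) > 0) {
    stop("invalid interval at line ", bad[1],
         ": require 0 <= start < end", call. = FALSE)
  }
  bad <- which(!out$kind %in% ELEMENT_KINDS)
  if (length(bad) > 0) {
    stop("unknown element kind '", out$kind[bad[1]], "' at line ", bad[1],
         "; expected one of: ", paste(ELEMENT_KINDS, collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write an annotated-element table
#'
#' Inverse of [read_elements()]: a header-less 5-column TSV in BED 0-based
#' half-open convention.
#'
#' @param elements Tibble with chrom, start, end, name, kind.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements <- function(elements, path) {
  readr::write_tsv(elements[, c("chrom", "start", "end", "name", "kind")],
                   path, col_names = FALSE)
  invisible(path)
}

#' In-silico restriction digestion of a linear sequence
#'
#' Scans the top strand for every occurrence of the enzyme's recognition
#' motif and cuts at `cut_offset` bases from the motif start. The fragments
#' tile `[region_start, region_start + nchar(seq))` without gaps or overlaps;
#' the molecule is treated as linear (no circular wrap). Overlapping motif
#' occurrences are resolved left to right.
#'
#' @param seq DNA sequence (character scalar or `Biostrings::DNAString`),
#'   case-insensitive.
#' @param region_start 0-based genomic start of the sequence.
#' @param enzyme One row of [restriction_enzymes()].
#' @param chrom Chromosome label carried into the output (default "chr11").
#' @return Tibble of fragments: `index`, `chrom`, `start`, `end`, `enzyme`,
#'   coordinate-ordered with strictly increasing indices.
#' @export
#' @examples
#' digest_sequence("GGAGATCTCC", 0, restriction_enzymes("BglII"))
digest_sequence <- function(seq, region_start, enzyme, chrom = "chr11") {
  validate_enzyme(enzyme)
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0) stop("empty sequence", call. = FALSE)
  if (!grepl("^[ACGTRYSWKMBDHVN]*$", seq)) {
    stop("sequence contains characters outside the IUPAC DNA alphabet",
         call. = FALSE)
  }
  hits <- Biostrings::matchPattern(enzyme$recognition,
                                   Biostrings::DNAString(seq))
  starts0 <- Biostrings::start(hits) - 1L  # 0-based motif starts
  # left-to-right greedy: drop occurrences overlapping an accepted one
  keep <- integer(0)
  last_end <- -1L
  for (s in starts0) {
    if (s > last_end) {
      keep <- c(keep, s)
      last_end <- s + nchar(enzyme$recognition) - 1L
    }
  }
  cuts <- keep + enzyme$cut_offset
  cuts <- cuts[cuts > 0 & cuts < nchar(seq)]
  bounds <- c(0L, as.integer(cuts), nchar(seq))
  tibble::tibble(
    index = seq_len(length(bounds) - 1L),
    chrom = chrom,
    start = region_start + bounds[-length(bounds)],
    end = region_start + bounds[-1],
    enzyme = enzyme$name
  )
}

#' Export a fragment map as BED
#'
#' @param fragments Output of [digest_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- tibble::tibble(
    chrom = fragments$chrom, start = fragments$start, end = fragments$end,
    name = paste0("frag_", fragments$index)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Locate primers on the fragment map and build an anchor's fragment axis
#'
#' Each primer must fall entirely inside one restriction fragment; a primer
#' straddling a cut site cannot report on a unique ligation junction and is
#' rejected. The axis is the coordinate-ordered set of distinct fragments
#' covered by test primers; two primers in the same fragment collapse to one
#' axis entry with a warning.
#'
#' @param primers Element tibble with kinds `anchor_primer` / `test_primer`.
#' @param fragments Fragment tibble from [digest_sequence()].
#' @param anchor_name Name of the anchor primer to use.
#' @return Tibble with one row per axis fragment (`role` = "anchor" first,
#'   then "test" rows in coordinate order): columns `role`, `primer`,
#'   `fragment`, `index`, `chrom`, `start`, `end`.
#' @export
locate_fragments <- function(primers, fragments, anchor_name) {
  primers <- primers[primers$kind %in% c("anchor_primer", "test_primer"), ]
  if (!anchor_name %in% primers$name[primers$kind == "anchor_primer"]) {
    stop("anchor primer '", anchor_name, "' not found", call. = FALSE)
  }
  find_fragment <- function(p_start, p_end, p_name) {
    inside <- fragments$start <= p_start & p_end <= fragments$end
    if (!any(inside)) {
      overlap <- fragments$start < p_end & p_start < fragments$end
      if (sum(overlap) > 1) {
        stop("primer '", p_name, "' straddles a restriction site",
             call. = FALSE)
      }
      stop("primer '", p_name, "' falls outside the fragment map",
           call. = FALSE)
    }
    which(inside)[1]
  }
  idx <- mapply(find_fragment, primers$start, primers$end, primers$name)
  located <- tibble::tibble(
    role = ifelse(primers$kind == "anchor_primer", "anchor", "test"),
    primer = primers$name,
    index = fragments$index[idx],
    chrom = fragments$chrom[idx],
    start = fragments$start[idx],
    end = fragments$end[idx]
  )
  anchor_row <- located[located$primer == anchor_name, ]
  tests <- located[located$role == "test", ]
  tests <- dplyr::arrange(tests, .data$start)
  dup <- duplicated(tests$index)
  if (any(dup)) {
    warning("primers ", paste(tests$primer[dup], collapse = ", "),
            " share a fragment with an earlier primer; axis entries merged",
            call. = FALSE)
    tests <- tests[!dup, ]
  }
  out <- dplyr::bind_rows(anchor_row, tests)
  out$fragment <- paste0("frag_", out$index)
  out[, c("role", "primer", "fragment", "index", "chrom", "start", "end")]
}
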