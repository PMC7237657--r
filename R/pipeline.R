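# Orchestration: run the analysis stages in dependency order from a single
# YAML (or list) configuration, with a manifest of outputs (md5 checksums)
# and a machine-parseable log. Stages: digest -> quant -> diff; fish; phase;
# methqc. Re-running with unchanged inputs and seed is bit-reproducible.

#' Run the analysis pipeline
#'
#' The configuration is a YAML file or an equivalent named list with
#' entries:
#' \describe{
#'   \item{inputs}{paths: `fasta`, `elements`, `bands`, `spots`, `snp`,
#'     `methylation` — stages whose inputs are absent are skipped unless
#'     requested explicitly via `stages`.}
#'   \item{params}{`enzyme` (default "BglII"), `region_start`, `anchor`,
#'     `control_samples`, `case_sample`, `theta`, and optional `fish` /
#'     `stats` / `methylation_ranges` sub-lists overriding the defaults of
#'     [fish_config()], [stat_config()], [methylation_ranges()].}
#'   \item{out_dir}{output directory.}
#'   \item{seed}{integer recorded in the log.}
#' }
#'
#' @param config Path to a YAML file or a named list.
#' @return Invisibly, a list with `manifest` (tibble of file, md5) and
#'   `outputs` (named paths). Fails with the offending path named when an
#'   input is missing; outputs written before a stage failure stay in the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  inputs <- cfg[["inputs"]] %||% list()
  params <- cfg[["params"]] %||% list()
  out_dir <- cfg[["out_dir"]] %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logln <- function(tag, msg) {
    writeLines(sprintf("%s\t%s", tag, msg), log_con)
  }
  logln("VERSION", as.character(utils::packageVersion("imprintloop")))
  logln("SEED", as.character(cfg[["seed"]] %||% NA))
  logln("CONFIG_HASH", digest_config(cfg))

  need <- function(key) {
    p <- inputs[[key]]
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) {
      stop("input file for '", key, "' not found: ", p, call. = FALSE)
    }
    p
  }
  fish_cfg <- do.call(fish_config, params[["fish"]] %||% list())
  stat_cfg <- do.call(stat_config, params[["stats"]] %||% list())
  meth_rng <- do.call(methylation_ranges,
                      params[["methylation_ranges"]] %||% list())

  outputs <- character()
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(as.data.frame(obj), p)
    outputs[[name]] <<- p
    logln("OUTPUT", p)
    p
  }

  fragments <- NULL
  axis <- NULL
  elements <- if (!is.null(need("elements"))) read_elements(inputs[["elements"]])

  if (!is.null(need("fasta"))) {
    seqs <- Biostrings::readDNAStringSet(inputs[["fasta"]])
    enz <- restriction_enzymes(params[["enzyme"]] %||% "BglII")
    fragments <- digest_sequence(seqs[[1]],
                                 params[["region_start"]] %||% 0L, enz,
                                 chrom = params[["chrom"]] %||% "chr11")
    write_fragments_bed(fragments, file.path(out_dir, "fragments.bed"))
    outputs[["fragments.bed"]] <- file.path(out_dir, "fragments.bed")
    logln("STAGE", "digest done")
    if (!is.null(elements)) {
      axis <- locate_fragments(elements, fragments,
                               params[["anchor_primer"]] %||%
                                 params[["anchor"]] %||%
                                 stop("params$anchor required",
                                      call. = FALSE))
    }
  }

  if (!is.null(need("bands"))) {
    bands <- normalize_bands(read_bands(inputs[["bands"]]))
    anchor <- params[["anchor"]] %||% bands$anchor[1]
    axis_arg <- if (!is.null(axis)) axis else
      sort(unique(bands$test[bands$anchor == anchor]))
    profiles <- dplyr::bind_rows(lapply(unique(bands$sample), function(sm) {
      build_looping_profile(bands, sm, anchor, axis_arg)
    }))
    emit(profiles, "profiles.tsv")
    logln("STAGE", "quant done")

    ctrl_samples <- params[["control_samples"]]
    case_sample <- params[["case_sample"]]
    if (!is.null(ctrl_samples) && !is.null(case_sample)) {
      per_assay <- function(samples) {
        sub <- bands[bands$sample %in% samples &
                       bands$anchor == anchor & !bands$undetectable_ctrl, ]
        tibble::tibble(test = sub$test, frequency = sub$frequency)
      }
      rois <- call_rois(per_assay(ctrl_samples), per_assay(case_sample),
                        stat_cfg)
      rois$anchor <- anchor
      if (!is.null(axis)) {
        rois <- dplyr::left_join(
          rois, axis[axis$role == "test",
                     c("fragment", "chrom", "start", "end")],
          by = c(test = "fragment"))
        if (!is.null(elements)) {
          rois <- build_interactome_table(rois, elements)
        }
      }
      emit(rois, "roi.tsv")
      logln("STAGE", "diff done")
    }
  }

  if (!is.null(need("spots"))) {
    res <- analyze_fish(read_spots(inputs[["spots"]]), fish_cfg,
                        line = params[["fish_line"]] %||% "line")
    emit(res$qc, "fish_qc.tsv")
    emit(res$alleles, "fish_alleles.tsv")
    emit(res$nuclei, "fish_nuclei.tsv")
    emit(res$summary, "fish_summary.tsv")
    logln("STAGE", "fish done")
  }

  if (!is.null(need("snp"))) {
    snp <- read_snp_signals(inputs[["snp"]])
    calls <- dplyr::bind_cols(
      snp["interaction"],
      quantify_allele_fraction(snp$signal_a, snp$signal_b,
                               theta = params[["theta"]] %||% 0.8))
    emit(calls, "allele_calls.tsv")
    logln("STAGE", "phase done")
  }

  if (!is.null(need("methylation"))) {
    meth <- classify_methylation_table(read_methylation(inputs[["methylation"]]),
                                       meth_rng)
    emit(meth, "methylation_status.tsv")
    logln("STAGE", "methqc done")
  }

  if (length(outputs) == 0) {
    stop("no stage had inputs to run", call. = FALSE)
  }
  manifest <- tibble::tibble(
    file = names(outputs),
    md5 = unname(tools::md5sum(unlist(outputs)))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  logln("STAGE", "manifest written")
  invisible(list(manifest = manifest, outputs = outputs,
                 out_dir = out_dir))
}

digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a human-readable summary report
#'
#' Collects whatever stage outputs are present in a pipeline output
#' directory into one markdown report: FISH category table (percentages at
#' 2 decimals), ROI table, allele calls, methylation status / subtype.
#'
#' @param out_dir A [run_pipeline()] output directory (or its return
#'   value).
#' @param path Report destination (default `report.md` inside `out_dir`).
#' @return `path`, invisibly.
#' @export
write_report <- function(out_dir, path = NULL) {
  if (is.list(out_dir)) out_dir <- out_dir$out_dir
  if (is.null(path)) path <- file.path(out_dir, "report.md")
  sections <- character()
  add <- function(...) sections <<- c(sections, ...)
  grab <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p)) readr::read_tsv(p, show_col_types = FALSE)
  }
  md_table <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.2f", x))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|")))
  }
  add("# Pipeline report", "")
  found <- FALSE
  fish <- grab("fish_summary.tsv")
  if (!is.null(fish)) {
    found <- TRUE
    add("## 3D FISH cohort summary", "",
        md_table(fish[, c("line", "n_nuclei", "pct_plus_plus",
                          "pct_plus_minus", "pct_minus_minus",
                          "allele_coloc_pct", "trans_pct")]), "")
  }
  roi <- grab("roi.tsv")
  if (!is.null(roi)) {
    found <- TRUE
    cols <- intersect(c("anchor", "test", "control_mean", "case_mean",
                        "p_adj", "stars", "category", "test_element"),
                      names(roi))
    add("## Differential regions of interaction", "",
        md_table(roi[, cols]), "")
  }
  calls <- grab("allele_calls.tsv")
  if (!is.null(calls)) {
    found <- TRUE
    add("## Allele-specificity calls", "", md_table(calls), "")
  }
  meth <- grab("methylation_status.tsv")
  if (!is.null(meth)) {
    found <- TRUE
    add("## ICR methylation status", "", md_table(meth), "")
  }
  if (!found) stop("no stage outputs found in ", out_dir, call. = FALSE)
  writeLines(sections, path)
  invisible(path)
}
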