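## Pipeline orchestration: simulate -> scan -> structure -> annotate ->
## tabulate/summarize -> report, driven by a single configuration, with a
## JSON run manifest recording parameters, seed and per-stage record counts.
## All intermediate tables are plain TSV with header comments naming the
## producing stage, so any stage can be re-run standalone.

#' Build and validate a pipeline configuration
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognized entries: `outdir` (required), `seed`, `genome` (a list of
#'   [genome_spec()] arguments used to simulate the input genome),
#'   `scan` (`max_evalue`, `end_tol`, `flank_len`), `annotate`
#'   (`max_evalue`, `window`), `discover` (`enabled`, `min_copies`,
#'   `len_range`, `min_tir`, `identity_cluster`).
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$outdir)) stop("config must name an `outdir`")
  defaults <- list(
    seed = 1L,
    scan = list(max_evalue = 1e-3, end_tol = 20L, flank_len = 500L),
    annotate = list(max_evalue = 1e-10, window = 100L),
    discover = list(enabled = FALSE, min_copies = 20L,
                    len_range = c(50L, 800L), min_tir = 8L,
                    identity_cluster = 0.80))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      miss <- setdiff(names(defaults[[nm]]), names(config[[nm]]))
      config[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  stopifnot(config$scan$max_evalue > 0, config$scan$end_tol >= 0,
            config$scan$flank_len > 0, config$annotate$max_evalue > 0,
            config$annotate$window >= 0)
  if (is.null(config$genome)) {
    stop("config must describe the synthetic input genome under `genome`")
  }
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full pipeline
#'
#' Executes the stages in order, writing every stage's outputs before the
#' next starts: simulate the genome bundle, scan for each planted family,
#' call TSDs and build target-site logos, annotate genomic context,
#' tabulate and summarize the distribution, and (optionally) run de novo
#' discovery. A `manifest.json` records parameters, seed and per-stage
#' record counts.
#'
#' @param config a `pipeline_config`, or anything [pipeline_config()]
#'   accepts.
#' @return invisibly, a list with the genome, records, distribution,
#'   summary, discovery results and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "mitescope",
                   version = as.character(utils::packageVersion("mitescope")),
                   seed = config$seed,
                   parameters = config[c("scan", "annotate", "discover")],
                   stages = list())
  stage_done <- function(name, counts) {
    manifest$stages[[name]] <<- counts
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  ## simulate
  gspec_args <- config$genome
  if (!is.data.frame(gspec_args$families)) {
    ## YAML gives a list of per-family maps
    gspec_args$families <- do.call(rbind, lapply(gspec_args$families,
                                                 as.data.frame))
  }
  gspec_args$seed <- config$seed
  if (!is.null(gspec_args$nesting_fractions)) {
    gspec_args$nesting_fractions <- unlist(gspec_args$nesting_fractions)
  }
  spec <- do.call(genome_spec, gspec_args)
  genome <- generate_genome(spec)
  write_genome(genome, file.path(outdir, "genome"))
  stage_done("simulate", list(chromosomes = nrow(genome$chrom_meta),
                              planted = nrow(genome$truth)))

  ## scan
  records <- scan_genome(genome, spec$families,
                         max_evalue = config$scan$max_evalue,
                         end_tol = config$scan$end_tol,
                         flank_len = config$scan$flank_len)
  write_insertions_tsv(records, file.path(outdir, "insertions.tsv"),
                       stage = "scan", params = config$scan)
  write_insertions_bed(records, file.path(outdir, "insertions.bed"))
  stage_done("scan", list(records = nrow(records)))

  ## structure: TSD calls per family + target-site logo
  rec_list <- list()
  for (f in seq_len(nrow(spec$families))) {
    frow <- spec$families[f, ]
    fr <- records[records$family == frow$family, , drop = FALSE]
    if (nrow(fr) == 0L) next
    fr <- call_tsds(fr, frow$superfamily,
                    family_pattern = frow$tsd_pattern)
    rec_list[[frow$family]] <- fr
    tsds <- fr$tsd_left[nzchar(fr$tsd_left)]
    if (length(tsds)) {
      write_pfm_tsv(build_pfm(tsds),
                    file.path(outdir, paste0("tsd_logo_", frow$family,
                                             ".tsv")))
    }
  }
  records <- do.call(rbind, c(rec_list, list(make.row.names = FALSE)))
  class(records) <- c("mite_insertions", "data.frame")
  write_insertions_tsv(records, file.path(outdir, "insertions_tsd.tsv"),
                       stage = "structure")
  stage_done("structure",
             list(records = nrow(records),
                  tsd_rule_matches = sum(records$tsd_matches_rule)))

  ## annotate
  refs <- reference_set(genome)
  records <- annotate_insertions(records, refs,
                                 max_evalue = config$annotate$max_evalue,
                                 window = config$annotate$window)
  write_insertions_tsv(records, file.path(outdir, "insertions_annotated.tsv"),
                       stage = "annotate", params = config$annotate)
  stage_done("annotate",
             list(records = nrow(records),
                  by_category = as.list(table(records$category))))

  ## tabulate + summarize
  dist <- tabulate_insertions(records, genome$chrom_meta,
                              genome_label = "synthetic")
  utils::write.table(as.data.frame(dist),
                     file.path(outdir, "distribution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sf_map <- stats::setNames(spec$families$superfamily, spec$families$family)
  summ <- mite_summary(dist, superfamilies = sf_map)
  jsonlite::write_json(
    list(grand_total = summ$grand_total, family = summ$family,
         superfamily = summ$superfamily, subgenome = summ$subgenome),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  stage_done("summarize", list(grand_total = summ$grand_total))

  ## discover (optional)
  discovered <- NULL
  if (isTRUE(config$discover$enabled)) {
    discovered <- discover_families(
      genome, spec$families,
      min_copies = config$discover$min_copies,
      len_range = config$discover$len_range,
      min_tir = config$discover$min_tir,
      identity_cluster = config$discover$identity_cluster)
    if (length(discovered)) {
      cons <- Biostrings::DNAStringSet(
        stats::setNames(vapply(discovered, `[[`, character(1),
                               "consensus_seq"),
                        paste0("candidate_", seq_along(discovered))))
      Biostrings::writeXStringSet(cons,
                                  file.path(outdir, "candidates.fa"))
    }
    stage_done("discover", list(candidates = length(discovered)))
  }

  invisible(list(genome = genome, records = records, distribution = dist,
                 summary = summ, discovered = discovered,
                 manifest = manifest))
}
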