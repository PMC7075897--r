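#' Read a run configuration file
#'
#' A flat declarative `key = value` format with `[section]` headers; one
#' section per pipeline stage plus a `[global]` section (`seed`, `outdir`,
#' `stages` as a comma-separated list).  Values are parsed as numbers where
#' possible, `true`/`false` as logicals.
#'
#' @param path configuration file.
#' @return A named list of sections, each a named list of values.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      parsed <- if (!is.na(num)) num
        else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
        else val
      out[[section]][[key]] <- parsed
    } else stopf("cannot parse config line: '%s'", ln)
  }
  out
}

stage_value <- function(config, stage, key, default) {
  v <- config[[stage]][[key]]
  if (is.null(v)) default else v
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages -- `proteomics` (candidate selection from a
#' count table), `chip` (simulated or file-based tracks, enrichment and
#' site pile-up) and `hic` (simulated or file-based contact matrices,
#' average-loop pile-up) -- writing stage outputs and a JSON manifest
#' recording inputs, parameters, seed and package version.  Per-stage seeds
#' are derived deterministically from the global seed and stage name, so a
#' fixed configuration reproduces its outputs exactly.
#'
#' @param config a configuration list (see [read_run_config()]) or the
#'   path to a configuration file.
#' @param outdir output directory (overrides the config's `outdir`).
#' @return The manifest, invisibly; written to `manifest.json` in the
#'   output directory.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(stage_value(config, "global", "seed", 1))
  if (is.null(outdir)) outdir <- stage_value(config, "global", "outdir", "proxireg_out")
  stages <- stage_value(config, "global", "stages", "")
  stages <- trimws(strsplit(as.character(stages), ",")[[1]])
  stages <- stages[nzchar(stages)]
  unknown <- setdiff(stages, c("proteomics", "chip", "hic"))
  if (length(unknown)) stopf("unknown stage(s): %s", paste(unknown, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "proxireg",
                   version = as.character(packageVersion("proxireg")),
                   seed = seed, stages = as.list(stages),
                   parameters = config, outputs = list())

  run_stage <- function(name, fun) {
    msg("stage ", name, " starting")
    res <- tryCatch(fun(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    msg("stage ", name, " done")
    res
  }

  if ("proteomics" %in% stages) {
    manifest$outputs$proteomics <- run_stage("proteomics", function() {
      counts_path <- config$proteomics$counts
      technique <- toupper(stage_value(config, "proteomics", "technique", "BIOID2"))
      if (is.null(counts_path)) {
        sim <- simulate_count_table(technique = technique,
                                    seed = derive_seed(seed, "proteomics"))
        tab <- sim$table
      } else {
        tab <- read_count_table(counts_path, technique,
                                nuclear_ids = config$proteomics$nuclear_ids)
      }
      fc <- filter_config(
        technique,
        min_peptides = config$proteomics$min_peptides,
        min_enrichment = stage_value(config, "proteomics", "min_enrichment", 2.5),
        pseudocount = stage_value(config, "proteomics", "pseudocount", 1),
        require_nuclear = stage_value(config, "proteomics", "require_nuclear",
                                      !is.null(config$proteomics$nuclear_ids)))
      sel <- select_candidates(tab, fc)
      out <- file.path(outdir, "candidates.tsv")
      write_count_table(sel, out)
      list(files = list(out), n_input = nrow(tab), n_selected = nrow(sel))
    })
  }

  if ("chip" %in% stages) {
    manifest$outputs$chip <- run_stage("chip", function() {
      sim <- simulate_chip_tracks(
        n_sites = stage_value(config, "chip", "n_sites", 200),
        peak_height = stage_value(config, "chip", "peak_height", 4),
        seed = derive_seed(seed, "chip"))
      enr <- enrichment_over_input(sim$chip, sim$input,
        pseudocount = stage_value(config, "chip", "pseudocount", 1))
      prof <- site_pileup(enr, sim$sites,
        flank = stage_value(config, "chip", "flank", 2000),
        stat = stage_value(config, "chip", "stat", "median"))
      out <- file.path(outdir, "chip_pileup.tsv")
      write_pileup_profile(prof, out)
      list(files = list(out), n_sites = nrow(prof$matrix),
           central_enrichment = prof$summary[which.min(abs(prof$positions))])
    })
  }

  if ("hic" %in% stages) {
    manifest$outputs$hic <- run_stage("hic", function() {
      hseed <- derive_seed(seed, "hic")
      n_loops <- stage_value(config, "hic", "n_loops", 20)
      loop_factor <- stage_value(config, "hic", "loop_factor", 3)
      chrom_length <- stage_value(config, "hic", "chrom_length", 5e6)
      anchors <- plant_loop_grid(chrom_length, n_loops, seed = hseed)
      cm <- simulate_contact_matrix(chrom_length = chrom_length,
                                    loop_anchors = anchors,
                                    loop_factor = loop_factor, seed = hseed)
      res <- average_loop(list(chrSim = cm), anchors,
        loop_pileup_config(
          pad = stage_value(config, "hic", "pad", 100e3),
          n_controls = stage_value(config, "hic", "controls", 10),
          seed = derive_seed(hseed, "controls")))
      prefix <- file.path(outdir, "hic_loop")
      write_pileup_result(res, prefix)
      list(files = list(paste0(prefix, ".normalized.tsv"),
                        paste0(prefix, ".raw.tsv"), paste0(prefix, ".json")),
           n_pairs = res$n_pairs_used, loop_strength = res$loop_strength)
    })
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  msg("manifest written to ", manifest_path)
  invisible(manifest)
}

#' Evenly spaced loop anchors for simulation
#'
#' Places `n` anchor pairs with jittered positions and separations between
#' 100 kb and 600 kb, away from the chromosome ends so padded pile-up
#' windows stay in bounds.
#'
#' @param chrom_length chromosome length in bp.
#' @param n number of anchor pairs.
#' @param pad margin kept at each end (default 150 kb).
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `pos_a`, `pos_b`, `separation`.
#' @export
plant_loop_grid <- function(chrom_length, n, pad = 150e3, chrom = "chrSim",
                            seed = 1L) {
  with_seed(seed, {
    pos_a <- runif(n, pad, chrom_length - pad - 600e3)
    sep <- runif(n, 100e3, 600e3)
    data.frame(chrom = chrom, pos_a = round(pos_a),
               pos_b = round(pos_a + sep),
               separation = round(sep))
  })
}
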