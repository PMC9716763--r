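#' Pipeline orchestration
#'
#' `run_pipeline()` drives the five run modes (simulate, amplify, dissect,
#' classify, pipeline) from a single config list, writing TSV/JSON/FASTA
#' reports. Runs are fully reproduced by (config, seed); every report
#' echoes the package version and the signature-table hash. A `no_call`
#' result is a result, not an error: the exit status is nonzero only for
#' I/O or configuration problems.
#'
#' @name io_cli
NULL

#' Build a run configuration
#'
#' @param mode one of simulate, amplify, dissect, classify, pipeline.
#' @param seed integer seed for every source of randomness.
#' @param out_dir output directory (created if needed).
#' @param ... mode-specific settings: `species`, `n`, `noise`
#'   (a [noise_model()]) for simulate/pipeline; `template_path`,
#'   `circular`, `max_mismatch` for amplify; `amplicon_path`,
#'   `genbank_path`, `panel_path` for dissect/classify.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "amplify", "dissect",
                                "classify", "pipeline"),
                       seed = 1L, out_dir = tempfile("igstyper_"), ...) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(c(list(mode = mode, seed = as.integer(seed),
                   out_dir = out_dir), list(...)),
            class = "run_config")
}

report_header <- function(table) {
  c(sprintf("# igstyper %s", as.character(utils::packageVersion("igstyper"))),
    sprintf("# signature_table_md5 %s", signature_table_hash(table)))
}

write_tsv_report <- function(df, path, table) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(table), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a configured pipeline
#'
#' @param config a [run_config()].
#' @param table signature table (default table if omitted).
#' @return list with `status` (0 on success), `outputs` (paths written) and
#'   mode-specific tables; errors from bad paths or configs propagate.
#' @export
run_pipeline <- function(config, table = default_signature_table()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  outputs <- character()
  result <- list()

  simulate_step <- function() {
    sp <- config$species %||% table_species(table)
    n <- config$n %||% length(sp)
    batch <- simulate_batch(sp, n = n, rng_seed = config$seed,
                            noise = config$noise)
    write_fasta(batch$amplicons, out("amplicons.fasta"))
    write_tsv_report(batch$truth, out("truth.tsv"), table)
    outputs <<- c(outputs, out("amplicons.fasta"), out("truth.tsv"))
    batch
  }

  classify_step <- function(amplicons, panel) {
    refs <- config$refs %||% synthetic_trna_refs("Ceratitis")
    calls <- classify_batch(amplicons, refs = refs, table = table,
                            panel = panel)
    write_tsv_report(calls, out("calls.tsv"), table)
    jsonlite::write_json(
      list(version = as.character(utils::packageVersion("igstyper")),
           signature_table_md5 = signature_table_hash(table),
           seed = config$seed, calls = calls),
      out("calls.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, out("calls.tsv"), out("calls.json"))
    calls
  }

  if (config$mode == "simulate") {
    result$batch <- simulate_step()

  } else if (config$mode == "amplify") {
    templates <- read_fasta(config$template_path)
    pr <- mito_primers()
    fwd <- config$fwd %||% pr$Mito_F
    rev <- config$rev %||% pr$Mito_R
    recs <- list()
    rows <- list()
    for (i in seq_along(templates)) {
      prods <- tryCatch(
        virtual_pcr(templates[[i]], fwd, rev,
                    circular = isTRUE(config$circular),
                    max_mismatch = config$max_mismatch %||% 3L,
                    template_id = names(templates)[i]),
        no_product_error = function(e) list())
      for (p in prods) {
        pid <- sprintf("%s_product%d", p$template_id, length(recs) + 1L)
        recs[[pid]] <- p$sequence
        rows[[length(rows) + 1]] <- data.frame(
          id = pid, template = p$template_id, start = p$start, end = p$end,
          strand = p$strand, length = p$length,
          fwd_mismatches = p$fwd_mismatches,
          rev_mismatches = p$rev_mismatches,
          multi_product = p$multi_product)
      }
    }
    hit_tab <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(id = character(), template = character(),
                 start = integer(), end = integer(), strand = character(),
                 length = integer(), fwd_mismatches = integer(),
                 rev_mismatches = integer(), multi_product = logical())
    if (length(recs) > 0) write_fasta(recs, out("products.fasta"))
    write_tsv_report(hit_tab, out("products.tsv"), table)
    outputs <- c(outputs, out("products.tsv"),
                 if (length(recs) > 0) out("products.fasta"))
    result$products <- hit_tab

  } else if (config$mode == "dissect") {
    amplicons <- read_fasta(config$amplicon_path)
    refs <- resolve_refs(config)
    rows <- list()
    spacers <- list()
    for (i in seq_along(amplicons)) {
      id <- names(amplicons)[i]
      d <- tryCatch(dissect_amplicon(amplicons[[i]], refs),
                    error = function(e) e)
      if (inherits(d, "error")) {
        rows[[i]] <- data.frame(id = id, igs1_len = NA, igs2_len = NA,
                                ile_identity = NA, gln_identity = NA,
                                met_identity = NA,
                                error = conditionMessage(d))
      } else {
        rows[[i]] <- data.frame(
          id = id, igs1_len = d$igs$igs1_len, igs2_len = d$igs$igs2_len,
          ile_identity = round(d$anchors$identity[["ile"]], 4),
          gln_identity = round(d$anchors$identity[["gln"]], 4),
          met_identity = round(d$anchors$identity[["met"]], 4),
          error = "")
        if (d$igs$igs1_len > 0)
          spacers[[paste0(id, "_igs1")]] <- d$igs$igs1_seq
        if (d$igs$igs2_len > 0)
          spacers[[paste0(id, "_igs2")]] <- d$igs$igs2_seq
      }
    }
    tab <- do.call(rbind, rows)
    write_tsv_report(tab, out("dissection.tsv"), table)
    if (length(spacers) > 0) write_fasta(spacers, out("spacers.fasta"))
    outputs <- c(outputs, out("dissection.tsv"),
                 if (length(spacers) > 0) out("spacers.fasta"))
    result$dissection <- tab

  } else if (config$mode == "classify") {
    amplicons <- if (is.null(config$amplicon_path)) character() else
      read_fasta(config$amplicon_path)
    panel <- if (!is.null(config$panel_path))
      read_fasta(config$panel_path) else config$panel
    if (length(amplicons) == 0) {
      calls <- data.frame(id = character(), status = character(),
                          species = character(), candidates = character(),
                          igs1_len = integer(), igs2_len = integer(),
                          method = character(), notes = character())
      write_tsv_report(calls, out("calls.tsv"), table)
      outputs <- c(outputs, out("calls.tsv"))
      result$calls <- calls
    } else {
      cfg2 <- config
      cfg2$refs <- resolve_refs(config)
      config <- cfg2
      result$calls <- classify_step(amplicons, panel)
    }

  } else if (config$mode == "pipeline") {
    batch <- simulate_step()
    panel <- config$panel %||% reference_panel(table)
    result$batch <- batch
    result$calls <- classify_step(batch$amplicons, panel)
  }

  list(status = 0L, outputs = outputs, result = result)
}

resolve_refs <- function(config) {
  if (!is.null(config$refs)) return(config$refs)
  if (!is.null(config$genbank_path)) {
    g <- read_annotated_genome(config$genbank_path)
    trna_refs_from_annotation(g)
  } else {
    synthetic_trna_refs("Ceratitis")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
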