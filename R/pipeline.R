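# Orchestration layer: each analysis stage as a batch function reading
# standard files and writing JSON/CSV reports. A thin command-line wrapper
# over these functions ships in inst/cli/skpentry.R.

.report_header <- function(params) {
  list(schema_version = 1L, package = "skpentry",
       params = params)
}

#' Batch peptide profiling
#'
#' Classifies peptides (from a FASTA file or a list of sequences) and writes
#' a characteristics table (id, length, hydrophobic count, charged count).
#'
#' @param input FASTA path or list of [peptide_sequence()] objects.
#' @param out optional CSV output path.
#' @return the profile data.frame, invisibly when written.
#' @export
run_seq_features <- function(input, out = NULL) {
  peps <- if (is.character(input) && length(input) == 1 &&
                file.exists(input)) read_peptides_fasta(input) else input
  tab <- profile_table(peps)
  if (!is.null(out)) {
    utils::write.csv(tab, out, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Batch trace fitting with directionality inference
#'
#' Reads kinetic-trace CSVs (site labels from their metadata headers or the
#' `sites` argument), selects the exponential order of each, and infers the
#' entry direction from the fast-phase time constants.
#'
#' @param paths character vector of trace CSV files.
#' @param sites optional character vector of site names overriding trace
#'   metadata.
#' @param z significance multiplier for ordering calls (default 2).
#' @param max_terms largest exponential order to consider.
#' @param out optional JSON output path.
#' @return list with `fits` (per-trace chosen fits), `selection` (chosen
#'   orders), `directionality` (a [infer_directionality()] report, `NULL`
#'   when fewer than two labelled sites).
#' @export
run_fit_traces <- function(paths, sites = NULL, z = 2, max_terms = 3,
                           out = NULL) {
  traces <- lapply(paths, read_trace)
  if (!is.null(sites)) {
    stopifnot(length(sites) == length(traces))
    for (i in seq_along(traces))
      traces[[i]]$label_site <- site_label(
        if (sites[i] %in% names(.SKP_SITES)) "Skp" else "OMP", sites[i])
  }
  sel <- lapply(traces, select_model, max_terms = max_terms)
  fits <- lapply(sel, `[[`, "fit")
  labs <- lapply(traces, `[[`, "label_site")
  have <- !vapply(labs, is.null, logical(1))
  direction <- NULL
  if (sum(have) >= 1) {
    direction <- infer_directionality(
      labs[have],
      tau1 = vapply(fits[have], function(f) f$time_constants[1], numeric(1)),
      se = vapply(fits[have], function(f) f$se$time_constants[1],
                  numeric(1)),
      z = z)
  }
  res <- list(fits = fits,
              selection = vapply(sel, `[[`, 0L, "n_terms"),
              directionality = direction)
  if (!is.null(out)) {
    rep <- .report_header(list(z = z, max_terms = max_terms,
                               inputs = as.character(paths)))
    rep$traces <- lapply(seq_along(fits), function(i) {
      fr <- fit_report_json(fits[[i]])
      fr$input <- as.character(paths[i])
      fr$site <- if (have[i]) labs[[i]]$site else NA
      fr
    })
    if (!is.null(direction))
      rep$directionality <- list(
        conclusion = direction$conclusion,
        monotonicity = direction$monotonicity,
        sites = direction$table$site, tau1_s = direction$table$tau1,
        se_s = direction$table$se)
    jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(res))
  }
  res
}

#' Fit an FCS curve and estimate the complex mass
#'
#' @param path FCS curve CSV.
#' @param n_relaxations relaxation components (default 2).
#' @param tau_d_ref,mw_ref optional dye reference (diffusion time in
#'   seconds, mass in kD) enabling the mass estimate.
#' @param weights see [fit_fcs()].
#' @param out optional JSON output path.
#' @return list with `fit` and `mw` (`NULL` without a reference).
#' @export
run_fit_fcs <- function(path, n_relaxations = 2, tau_d_ref = NULL,
                        mw_ref = NULL, weights = "uniform", out = NULL) {
  fit <- fit_fcs(read_fcs_curve(path), n_relaxations = n_relaxations,
                 weights = weights)
  mw <- NULL
  if (!is.null(tau_d_ref) && !is.null(mw_ref))
    mw <- estimate_mw(fit$tau_d, tau_d_ref, mw_ref, tau_d_se = fit$se$tau_d)
  if (!is.null(out)) {
    fcs_report_json(fit, mw, out)
    return(invisible(list(fit = fit, mw = mw)))
  }
  list(fit = fit, mw = mw)
}

#' Full entry analytics for trajectory files
#'
#' Runs [entry_report()] on each trajectory file and (optionally) writes a
#' JSON report bundle plus per-frame CSV series (entry coordinate, gate
#' distances, bridge counts) per input.
#'
#' @param paths trajectory files (`.pdb` or `.xyz`).
#' @param out_dir optional output directory for reports and series.
#' @param d_close,r_on,r_off,final_window,sustain see [entry_report()].
#' @return list of `entry_report` objects named by input file.
#' @export
run_analyze_traj <- function(paths, out_dir = NULL, d_close = 15,
                             r_on = 4.5, r_off = 6.0, final_window = 0.1,
                             sustain = 5) {
  reports <- list()
  for (p in paths) {
    traj <- read_trajectory(p)
    rep <- entry_report(traj, final_window = final_window,
                        sustain = sustain, d_close = d_close,
                        r_on = r_on, r_off = r_off)
    reports[[as.character(p)]] <- rep
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      stem <- tools::file_path_sans_ext(basename(p))
      j <- .report_header(rep$params)
      j$input <- as.character(p)
      j$verdict <- rep$verdict
      j$terminus_first <- rep$terminus_first
      j$crossing_frames <- as.list(rep$crossing_frames)
      j$max_delta_z <- as.list(rep$max_delta_z)
      j$gate_open_fraction <- rep$gate_open_fraction
      j$bridge_chain <- rep$bridge_chain
      j$events <- rep$events
      jsonlite::write_json(j, file.path(out_dir, paste0(stem, "_report.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.csv(rep$delta_z,
                       file.path(out_dir, paste0(stem, "_delta_z.csv")),
                       row.names = FALSE)
      utils::write.csv(rep$gate,
                       file.path(out_dir, paste0(stem, "_gate.csv")),
                       row.names = FALSE)
      utils::write.csv(rep$bridge_counts,
                       file.path(out_dir, paste0(stem, "_bridges.csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(out_dir)) invisible(reports) else reports
}

#' Generate a bundled scenario dataset on disk
#'
#' Writes the scripted trajectory (both supported formats) and its
#' ground-truth log for a bundled scenario.
#'
#' @param scenario scenario name (see [scenario_names()]) or an
#'   [entry_scenario()].
#' @param out_dir output directory.
#' @param seed RNG seed (ignored when a scenario object is supplied).
#' @param formats subset of `c("xyz", "pdb")`.
#' @return list with `trajectory`, `log` and `files`, invisibly.
#' @export
run_simulate <- function(scenario, out_dir, seed = 1,
                         formats = c("xyz", "pdb")) {
  if (is.character(scenario)) scenario <- entry_scenario(scenario, seed)
  stopifnot(inherits(scenario, "entry_scenario"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- gen_entry_trajectory(scenario)
  stem <- file.path(out_dir, sprintf("%s_seed%d", scenario$name,
                                     scenario$seed))
  files <- character(0)
  for (fmt in formats) {
    f <- paste0(stem, ".", fmt)
    write_trajectory(gen$trajectory, f, format = fmt)
    files <- c(files, f)
  }
  logf <- paste0(stem, "_truth.json")
  jsonlite::write_json(
    list(scenario = gen$log$scenario, seed = gen$log$seed,
         verdict = gen$log$verdict, terminus_first = gen$log$terminus_first,
         crossing_frames = as.list(gen$log$crossing_frames),
         events = gen$log$events, gate_open = gen$log$gate_open,
         n_frames = gen$log$n_frames),
    logf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trajectory = gen$trajectory, log = gen$log,
                 files = c(files, logf)))
}
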