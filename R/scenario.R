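#' Load and validate a scenario configuration
#'
#' Scenario files are YAML (\code{.yaml}/\code{.yml}) or JSON (\code{.json})
#' with top-level keys \code{metadata}, \code{trials}, \code{transition},
#' \code{economics} and \code{simulation}. The transition block's
#' \code{life_table} is either inline (\code{age} and \code{qx} arrays) or a
#' path to an \code{age,qx} CSV, resolved relative to the configuration
#' file. Every constraint violation is reported with the offending key.
#'
#' @param path Path to the scenario file.
#' @return A validated \code{"cea_scenario"} object (see [synth_scenario()]).
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("trials", "transition", "economics", "simulation")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("scenario is missing top-level key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ctx <- function(key, expr) {
    tryCatch(expr, error = function(e) {
      stop("scenario key '", key, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  tr <- raw$transition
  lt <- tr$life_table
  lt <- if (is.character(lt)) {
    lt_path <- if (file.exists(lt)) lt else file.path(dirname(path), lt)
    ctx("transition.life_table", read_life_table(lt_path))
  } else {
    ctx("transition.life_table", life_table(unlist(lt$age), unlist(lt$qx)))
  }
  transition <- ctx("transition", markov_inputs(
    recurrence_by_year = unlist(tr$recurrence_by_year),
    death_hr_by_mrs = unlist(tr$death_hr_by_mrs),
    recurrent_outcome_dist = unlist(tr$recurrent_outcome_dist),
    life_table = lt,
    recurrence_after_year10 = tr$recurrence_after_year10,
    hr_method = tr$hr_method %||% "multiply",
    event_order = tr$event_order %||% "death_first"))
  ec <- raw$economics
  economics <- ctx("economics", econ_params(
    utilities = unlist(ec$utilities),
    first_year_cost_by_mrs = unlist(ec$first_year_cost_by_mrs),
    longterm_annual_cost_by_mrs = unlist(ec$longterm_annual_cost_by_mrs),
    evt_procedure_cost = ec$evt_procedure_cost,
    recurrent_stroke_acute_cost = ec$recurrent_stroke_acute_cost,
    discount_rate = ec$discount_rate %||% 0.03))
  trials <- list()
  for (t in raw$trials) {
    if (is.null(t$name)) stop("scenario key 'trials': every trial needs a name",
                              call. = FALSE)
    for (a in t$arms) {
      arm <- ctx(paste0("trials.", t$name),
                 trial_arm(t$name, a$strategy, a$n, unlist(a$dist),
                           mrs03_share = a$mrs03_share))
      trials[[t$name]][[arm$strategy]] <- arm
    }
    if (!all(c("EVT", "BMC") %in% names(trials[[t$name]]))) {
      stop("scenario key 'trials.", t$name,
           "': needs both an EVT and a BMC arm", call. = FALSE)
    }
  }
  if (length(trials) == 0) stop("scenario defines no trials", call. = FALSE)
  sim <- raw$simulation
  simulation <- list(start_age = as.numeric(sim$start_age %||% 67),
                     wtp = as.numeric(sim$wtp %||% 1e5),
                     psa_iterations = as.integer(sim$psa_iterations %||% 30000L),
                     dsa_spread = as.numeric(sim$dsa_spread %||% 0.25),
                     seed = as.integer(sim$seed %||% 1L))
  if (simulation$wtp < 0) stop("scenario key 'simulation.wtp': must be >= 0",
                               call. = FALSE)
  structure(list(metadata = raw$metadata %||%
                   list(name = "unnamed", currency_year = 2022L,
                        description = ""),
                 trials = trials,
                 transition = transition,
                 economics = economics,
                 simulation = simulation),
            class = "cea_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cea_scenario <- function(x, ...) {
  cat("CEA scenario '", x$metadata$name, "' (USD ",
      x$metadata$currency_year, ")\n", sep = "")
  cat("  trials:", paste(names(x$trials), collapse = ", "), "\n")
  cat(sprintf("  start age %d | WTP $%s/QALY | discount %.1f%%/yr\n",
              x$simulation$start_age,
              format(x$simulation$wtp, big.mark = ",", scientific = FALSE),
              100 * x$economics$discount_rate))
  invisible(x)
}

# plain-list representation used for serialization and hashing
.scenario_to_list <- function(scenario, life_table_ref = NULL) {
  tr <- scenario$transition
  ec <- scenario$economics
  lt_repr <- if (is.null(life_table_ref)) {
    list(age = tr$life_table$age, qx = tr$life_table$qx)
  } else life_table_ref
  list(
    metadata = scenario$metadata,
    trials = unname(lapply(scenario$trials, function(arms) {
      list(name = arms[[1]]$trial,
           arms = unname(lapply(arms, function(a) {
             out <- list(strategy = a$strategy, n = a$n,
                         dist = as.numeric(a$dist))
             if (!is.null(a$mrs03_share)) out$mrs03_share <- a$mrs03_share
             out
           })))
    })),
    transition = list(recurrence_by_year = tr$recurrence_by_year,
                      recurrence_after_year10 = tr$recurrence_after_year10,
                      death_hr_by_mrs = tr$death_hr_by_mrs,
                      recurrent_outcome_dist = tr$recurrent_outcome_dist,
                      hr_method = tr$hr_method,
                      event_order = tr$event_order,
                      life_table = lt_repr),
    economics = list(utilities = ec$utilities,
                     first_year_cost_by_mrs = ec$first_year_cost_by_mrs,
                     longterm_annual_cost_by_mrs = ec$longterm_annual_cost_by_mrs,
                     evt_procedure_cost = ec$evt_procedure_cost,
                     recurrent_stroke_acute_cost = ec$recurrent_stroke_acute_cost,
                     discount_rate = ec$discount_rate),
    simulation = scenario$simulation
  )
}

#' Write a scenario configuration to disk
#'
#' @param scenario A \code{"cea_scenario"}.
#' @param path Output path; extension selects YAML or JSON.
#' @param life_table_csv If non-NULL, the life table is written to this CSV
#'   path (relative paths resolve against the scenario file's directory) and
#'   referenced from the config; otherwise it is inlined.
#' @return \code{path}, invisibly.
#' @export
write_scenario <- function(scenario, path, life_table_csv = NULL) {
  stopifnot(inherits(scenario, "cea_scenario"))
  ref <- NULL
  if (!is.null(life_table_csv)) {
    abs <- if (grepl("^(/|[A-Za-z]:)", life_table_csv)) life_table_csv
           else file.path(dirname(path), life_table_csv)
    write_life_table(scenario$transition$life_table, abs)
    ref <- life_table_csv
  }
  lst <- .scenario_to_list(scenario, life_table_ref = ref)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

# md5 of an in-memory string (via a temp file; tools::md5sum is file-based)
.md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

#' Hash of a scenario's canonical serialization
#'
#' @param scenario A \code{"cea_scenario"}.
#' @return MD5 hex digest of the canonical YAML serialization.
#' @export
scenario_hash <- function(scenario) {
  .md5_string(yaml::as.yaml(.scenario_to_list(scenario), precision = 15))
}

#' Base-case cost-effectiveness analysis of a scenario
#'
#' Runs the cohort model for both strategies in every trial and in the
#' participant-weighted pooled cohort, and compares them at the scenario's
#' willingness-to-pay threshold. The result's \code{table} mirrors the
#' standard CEA table layout: per-strategy lifetime cost and effectiveness
#' plus incremental columns and the ICER-or-sentinel.
#'
#' @param scenario A \code{"cea_scenario"} (from [load_scenario()] or
#'   [synth_scenario()]).
#' @param pooled Include the pooled comparison (default TRUE).
#' @return Object of class \code{"cea_analysis"}: per-cohort list of
#'   \code{evt}/\code{bmc} [run_strategy()] results and the
#'   \code{comparison}, plus the summary \code{table} and the scenario.
#' @export
run_scenario <- function(scenario, pooled = TRUE) {
  stopifnot(inherits(scenario, "cea_scenario"))
  sim <- scenario$simulation
  cohorts <- lapply(scenario$trials, function(arms) {
    list(evt_dist = arms$EVT$dist, bmc_dist = arms$BMC$dist)
  })
  if (pooled && length(scenario$trials) > 1) {
    evt_arms <- lapply(scenario$trials, `[[`, "EVT")
    bmc_arms <- lapply(scenario$trials, `[[`, "BMC")
    cohorts$Pooled <- list(evt_dist = pool_arms(unname(evt_arms)),
                           bmc_dist = pool_arms(unname(bmc_arms)))
  }
  comparisons <- lapply(cohorts, function(co) {
    evt <- run_strategy(co$evt_dist, "EVT", scenario$transition,
                        scenario$economics, start_age = sim$start_age)
    bmc <- run_strategy(co$bmc_dist, "BMC", scenario$transition,
                        scenario$economics, start_age = sim$start_age)
    list(evt = evt, bmc = bmc,
         comparison = compare_strategies(evt, bmc, wtp = sim$wtp))
  })
  table <- do.call(rbind, Map(function(name, co) {
    cmp <- co$comparison
    data.frame(cohort = name,
               cost_bmc = co$bmc$total_cost,
               cost_evt = co$evt$total_cost,
               incr_cost = cmp$delta_cost,
               qaly_bmc = co$bmc$total_qalys,
               qaly_evt = co$evt$total_qalys,
               incr_qalys = cmp$delta_qalys,
               icer = cmp$icer_label,
               classification = cmp$classification,
               nmb = cmp$nmb_delta,
               stringsAsFactors = FALSE)
  }, names(comparisons), comparisons))
  rownames(table) <- NULL
  structure(list(comparisons = comparisons, table = table,
                 scenario = scenario),
            class = "cea_analysis")
}

#' @export
print.cea_analysis <- function(x, ...) {
  cat("Lifetime cost-effectiveness: EVT vs BMC\n")
  cat(sprintf("  WTP $%s/QALY | discount %.1f%%/yr | start age %d\n\n",
              format(x$scenario$simulation$wtp, big.mark = ",", scientific = FALSE),
              100 * x$scenario$economics$discount_rate,
              x$scenario$simulation$start_age))
  t <- x$table
  disp <- data.frame(Cohort = t$cohort,
                     `Cost BMC` = sprintf("$%s", format(round(t$cost_bmc),
                                                        big.mark = ",")),
                     `Cost EVT` = sprintf("$%s", format(round(t$cost_evt),
                                                        big.mark = ",")),
                     `Incr.Cost` = sprintf("$%s", format(round(t$incr_cost),
                                                         big.mark = ",")),
                     `QALY BMC` = sprintf("%.2f", t$qaly_bmc),
                     `QALY EVT` = sprintf("%.2f", t$qaly_evt),
                     `Incr.QALY` = sprintf("%.2f", t$incr_qalys),
                     ICER = t$icer,
                     check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cea_analysis <- function(object, ...) {
  print(object)
  invisible(object$table)
}

#' Consistency check of a published-style CEA table
#'
#' Recomputes the incremental columns of a CEA table from its per-strategy
#' totals and flags any printed incremental value that disagrees by more
#' than \code{tol_cost} dollars or \code{tol_qaly} QALYs. This surfaces
#' internal inconsistencies in published tables rather than silently fixing
#' them.
#'
#' @param table Data frame with columns \code{cohort}, \code{cost_bmc},
#'   \code{cost_evt}, \code{incr_cost}, \code{qaly_bmc}, \code{qaly_evt},
#'   \code{incr_qalys} (printed incrementals may be NA).
#' @param tol_cost Dollar tolerance (default $1).
#' @param tol_qaly QALY tolerance (default 0.01).
#' @return Data frame with recomputed incrementals, discrepancies, and
#'   logical flags \code{cost_mismatch} / \code{qaly_mismatch}.
#' @export
check_cea_table <- function(table, tol_cost = 1, tol_qaly = 0.01) {
  need <- c("cohort", "cost_bmc", "cost_evt", "incr_cost",
            "qaly_bmc", "qaly_evt", "incr_qalys")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("check_cea_table: table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(cohort = table$cohort,
                    incr_cost_printed = table$incr_cost,
                    incr_cost_recomputed = table$cost_evt - table$cost_bmc,
                    incr_qalys_printed = table$incr_qalys,
                    incr_qalys_recomputed = table$qaly_evt - table$qaly_bmc,
                    stringsAsFactors = FALSE)
  out$cost_discrepancy <- out$incr_cost_printed - out$incr_cost_recomputed
  out$qaly_discrepancy <- out$incr_qalys_printed - out$incr_qalys_recomputed
  # small slack so values exactly at the tolerance are not flagged
  out$cost_mismatch <- !is.na(out$cost_discrepancy) &
    abs(out$cost_discrepancy) > tol_cost + 1e-9
  out$qaly_mismatch <- !is.na(out$qaly_discrepancy) &
    abs(out$qaly_discrepancy) > tol_qaly + 1e-9
  out
}

#' Write analysis outputs and a run manifest
#'
#' Writes \code{cea_table.csv}, per-strategy pooled cycle traces
#' (\code{trace_EVT.csv}, \code{trace_BMC.csv}), optional PSA exports
#' (\code{psa_points.csv}, \code{ceac.csv}) and tornado export
#' (\code{tornado.csv}), plus \code{run_manifest.json} listing every file
#' with its content hash, the scenario hash and seed. Reruns with the same
#' scenario and seed reproduce byte-identical files.
#'
#' @param analysis A [run_scenario()] result.
#' @param outdir Output directory (created if needed).
#' @param psa Optional [run_psa()] result.
#' @param dsa Optional [one_way_dsa()] result.
#' @param ceac_grid WTP grid for the CEAC export when \code{psa} is given.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(analysis, outdir, psa = NULL, dsa = NULL,
                          ceac_grid = seq(0, 2e5, by = 5000)) {
  stopifnot(inherits(analysis, "cea_analysis"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wrote <- character()
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    wrote <<- c(wrote, name)
  }
  emit(analysis$table, "cea_table.csv")
  pooled <- analysis$comparisons[[length(analysis$comparisons)]]
  emit(pooled$evt$trace, "trace_EVT.csv")
  emit(pooled$bmc$trace, "trace_BMC.csv")
  omitted <- character()
  if (!is.null(psa)) {
    emit(psa$points, "psa_points.csv")
    emit(ceac(psa, ceac_grid), "ceac.csv")
  } else {
    omitted <- c(omitted, "psa_points.csv", "ceac.csv")
  }
  if (!is.null(dsa)) {
    emit(as.data.frame(dsa), "tornado.csv")
  } else {
    omitted <- c(omitted, "tornado.csv")
  }
  hashes <- as.list(tools::md5sum(file.path(outdir, wrote)))
  names(hashes) <- wrote
  manifest <- list(
    scenario_name = analysis$scenario$metadata$name,
    scenario_hash = scenario_hash(analysis$scenario),
    seed = analysis$scenario$simulation$seed,
    package_version = as.character(utils::packageVersion("evtcea")),
    files = hashes,
    omitted = as.list(omitted)
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
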