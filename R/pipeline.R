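#' Configuration of an analysis run
#'
#' Collects the knobs of the full analysis chain.  All defaults are
#' recorded in the run log for provenance.
#'
#' @param background_method baseline model passed to
#'   \code{\link{subtract_background}} (\code{"none"} skips subtraction).
#' @param background_degree degree for \code{"polynomial"}.
#' @param indexing_tolerance relative tolerance for
#'   \code{\link{index_lattice}}.
#' @param lorentz_exponent exponent for \code{\link{lorentz_correct}}.
#' @param reference_fraction reference D2O fraction for phasing and
#'   reconstruction.
#' @param grid_step NSLD grid step (\eqn{\AA}).
#' @param min_orders minimum number of usable Bragg orders at the
#'   reference contrast for a parameter extraction (default 3: with fewer
#'   coefficients the reconstructed profile is too coarse for a credible
#'   headgroup fit, and such conditions report the lattice constant only).
#' @param vols a \code{\link{volume_set}}.
#' @param phase_vector optional user-supplied sign vector (+1/-1 per
#'   order), enabling single-contrast runs where phasing by contrast
#'   variation is impossible.
#' @param out_dir optional output directory for artifacts; \code{NULL}
#'   writes nothing.
#' @param seed integer seed (recorded; the analysis chain itself is
#'   deterministic).
#' @param verbose print progress messages.
#' @return A \code{"run_config"} list.
#' @export
run_config <- function(background_method = "none", background_degree = 2,
                       indexing_tolerance = 0.01, lorentz_exponent = 1,
                       reference_fraction = 0.08, grid_step = 0.1,
                       min_orders = 3L, vols = volume_set(),
                       phase_vector = NULL,
                       out_dir = NULL, seed = 1L, verbose = FALSE) {
  if (!is.numeric(seed) || seed != round(seed))
    stop("seed must be an integer")
  if (min_orders < 1) stop("min_orders must be >= 1")
  structure(list(background_method = background_method,
                 background_degree = background_degree,
                 indexing_tolerance = indexing_tolerance,
                 lorentz_exponent = lorentz_exponent,
                 reference_fraction = reference_fraction,
                 grid_step = grid_step, min_orders = as.integer(min_orders),
                 vols = vols,
                 phase_vector = phase_vector, out_dir = out_dir,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from a flat key=value text file
#'
#' Lines of the form \code{key = value}; \code{#} starts a comment.
#' Recognised keys mirror the arguments of \code{\link{run_config}}, plus
#' \code{V_l}, \code{V_c}, \code{V_w} for the volume set and
#' \code{phase_vector} as comma-separated signs (e.g. \code{-1,-1,1,-1}).
#'
#' @param path file path.
#' @return A \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln)) stop("not a key=value line: '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  num <- function(k, d) if (is.null(kv[[k]])) d else as.numeric(kv[[k]])
  vols <- volume_set(V_l = num("V_l", 1400), V_c = num("V_c", 1175),
                     V_w = num("V_w", 30))
  pv <- if (!is.null(kv$phase_vector))
    as.integer(strsplit(kv$phase_vector, ",")[[1]]) else NULL
  run_config(
    background_method = if (is.null(kv$background_method)) "none"
                        else kv$background_method,
    background_degree = num("background_degree", 2),
    indexing_tolerance = num("indexing_tolerance", 0.01),
    lorentz_exponent = num("lorentz_exponent", 1),
    reference_fraction = num("reference_fraction", 0.08),
    grid_step = num("grid_step", 0.1),
    min_orders = num("min_orders", 3),
    vols = vols, phase_vector = pv,
    out_dir = kv$out_dir, seed = num("seed", 1))
}

# exclusion windows for background fitting: coarse peak detection on the
# raw scan, window = centre +/- 5 widths
.auto_exclusion <- function(d) {
  pk <- tryCatch(fit_peaks(d), error = function(e) NULL)
  if (is.null(pk)) return(list())
  lapply(seq_len(nrow(pk)), function(i)
    c(pk$center[i] - 5 * pk$width[i], pk$center[i] + 5 * pk$width[i]))
}

#' Run the full analysis chain for one condition
#'
#' Orchestrates read, background subtraction, peak fitting, lattice
#' indexing, Lorentz correction, contrast-variation phasing, NSLD
#' reconstruction, and parameter extraction for one experimental condition
#' measured at one or more D2O contrasts.
#'
#' Non-lamellar or coexisting-lamellar conditions, and lamellar conditions
#' with fewer than two usable Bragg orders, yield a lattice-only result:
#' the phase class and lattice constant(s) are reported and the bilayer
#' parameters are marked unavailable, with the reason in \code{$reason}.
#' Single-contrast conditions require a user-supplied
#' \code{phase_vector} in the config.
#'
#' @param scans a list of \code{\link{diffractogram}} objects (or file
#'   paths) for one condition, one per D2O contrast.
#' @param cfg a \code{\link{run_config}}.
#' @param label condition label used in reports.
#' @return A \code{"condition_result"}: list with \code{label},
#'   \code{phase_class}, \code{assignment}, \code{sf}, \code{phases},
#'   \code{profile}, \code{parameters} (NULL when unavailable),
#'   \code{reason} (why parameters are unavailable, or NULL), \code{log}.
#' @export
run_condition <- function(scans, cfg = run_config(), label = "condition") {
  stopifnot(inherits(cfg, "run_config"))
  if (inherits(scans, "diffractogram")) scans <- list(scans)
  scans <- lapply(scans, function(s)
    if (is.character(s)) read_diffractogram(s) else s)
  stopifnot(all(vapply(scans, inherits, TRUE, "diffractogram")))
  say <- function(...) if (cfg$verbose) message(...)
  log <- list(package_version = as.character(utils::packageVersion("lamellar")),
              seed = cfg$seed, config = unclass(cfg)[
                setdiff(names(unclass(cfg)), "vols")],
              volumes = unclass(cfg$vols), steps = character(0))
  note <- function(msg) log$steps <<- c(log$steps, msg)

  fracs <- vapply(scans, function(s)
    if (is.null(s$meta$x_D2O)) NA_real_ else s$meta$x_D2O, 0)
  if (anyNA(fracs)) stop("every scan needs x_D2O metadata")

  # reduction per contrast
  reduced <- lapply(scans, function(s) {
    if (cfg$background_method != "none") {
      s <- subtract_background(s, cfg$background_method,
                               cfg$background_degree,
                               exclude = .auto_exclusion(s))
    }
    s
  })
  peaksets <- lapply(reduced, fit_peaks)
  assigns <- lapply(peaksets, index_lattice,
                    tolerance = cfg$indexing_tolerance)

  i_ref <- which.min(abs(fracs - cfg$reference_fraction))
  assignment <- assigns[[i_ref]]
  phase_class <- assignment$phase_class
  note(sprintf("indexed %d contrast(s); reference phase class: %s",
               length(scans), phase_class))

  result <- list(label = label, phase_class = phase_class,
                 assignment = assignment, sf = NULL, phases = NULL,
                 profile = NULL, parameters = NULL, reason = NULL,
                 log = log)
  class(result) <- "condition_result"
  finish <- function(res) {
    res$log$steps <- log$steps
    if (!is.null(cfg$out_dir)) .write_artifacts(res, cfg)
    res
  }

  if (phase_class != "lamellar") {
    result$reason <- paste0("phase class '", phase_class,
                            "': bilayer parameters only defined for a ",
                            "single lamellar lattice")
    note(result$reason)
    return(finish(result))
  }

  lamellar_ok <- vapply(assigns, function(a)
    a$phase_class == "lamellar", TRUE)
  if (!all(lamellar_ok)) {
    keep <- which(lamellar_ok)
    note(sprintf("dropping %d non-lamellar contrast(s) from phasing",
                 sum(!lamellar_ok)))
  } else keep <- seq_along(scans)

  sf_list <- lapply(keep, function(i)
    lorentz_correct(assigns[[i]], p = cfg$lorentz_exponent,
                    x_D2O = fracs[i]))
  sf_all <- if (length(sf_list) > 1L) combine_sf(sf_list) else sf_list[[1]]
  result$sf <- sf_all

  n_orders <- length(unique(sf_all$order[sf_all$x_D2O ==
                                           fracs[i_ref]]))
  if (n_orders < cfg$min_orders) {
    result$reason <- sprintf(
      "only %d usable Bragg order(s), need %d: too few for a meaningful profile",
      n_orders, cfg$min_orders)
    note(result$reason)
    return(finish(result))
  }

  if (length(unique(fracs[keep])) >= 2L) {
    phases <- assign_phases(sf_all,
                            reference_fraction = cfg$reference_fraction)
    note(sprintf("phases from %d contrasts: %s",
                 length(unique(fracs[keep])),
                 paste(ifelse(phases$nu > 0, "+", "-"), collapse = " ")))
  } else if (!is.null(cfg$phase_vector)) {
    ords <- sort(unique(sf_all$order))
    if (length(cfg$phase_vector) < max(ords))
      stop("phase_vector shorter than the highest detected order")
    phases <- cfg$phase_vector[ords]
    note("phases supplied by user (single-contrast run)")
  } else {
    result$reason <- paste("single contrast and no user phase vector:",
                           "phases undeterminable")
    note(result$reason)
    return(finish(result))
  }
  result$phases <- phases

  sf_ref <- sf_all[abs(sf_all$x_D2O - fracs[i_ref]) < 1e-9, ]
  attr(sf_ref, "D") <- attr(sf_all, "D")
  attr(sf_ref, "p") <- attr(sf_all, "p")
  class(sf_ref) <- c("sf_table", "data.frame")
  profile <- reconstruct_nsld(sf_ref, phases, grid_step = cfg$grid_step)
  result$profile <- profile

  db <- tryCatch(headgroup_peak_to_peak(profile), error = function(e) e)
  if (inherits(db, "error")) {
    result$reason <- paste("headgroup fit failed:", conditionMessage(db))
    note(result$reason)
    return(finish(result))
  }
  D <- assignment$lattices[[1]]$D
  D_se <- assignment$lattices[[1]]$D_se
  pars <- tryCatch(
    bilayer_parameters(D, db$value, se_D = D_se, se_D_B = db$se,
                       vols = cfg$vols,
                       meta = c(list(label = label),
                                scans[[i_ref]]$meta[
                                  intersect(c("temperature_C",
                                              "relative_humidity"),
                                            names(scans[[i_ref]]$meta))])),
    error = function(e) e)
  if (inherits(pars, "error")) {
    result$reason <- paste("parameter chain failed:",
                           conditionMessage(pars))
    note(result$reason)
    return(finish(result))
  }
  result$parameters <- pars
  note("complete parameter set extracted")
  finish(result)
}

.write_artifacts <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(cfg$out_dir, gsub("[^A-Za-z0-9_.-]", "_", res$label))
  to_json <- function(x, path)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  to_json(list(phase_class = res$phase_class,
               lattices = res$assignment$lattices,
               assignment = res$assignment$assignment,
               residuals = res$assignment$residuals,
               peaks = as.data.frame(res$assignment$peaks)),
          paste0(stem, "_lattice.json"))
  if (!is.null(res$sf))
    to_json(c(list(p = attr(res$sf, "p"), D = attr(res$sf, "D")),
              list(rows = as.data.frame(res$sf))),
            paste0(stem, "_structure_factors.json"))
  if (!is.null(res$phases) && inherits(res$phases, "phase_assignment"))
    to_json(list(nu = res$phases$nu, fits = res$phases$fits,
                 reference_fraction = res$phases$reference_fraction,
                 boundary_c = res$phases$boundary_c),
            paste0(stem, "_phases.json"))
  if (!is.null(res$profile))
    write_nsld_profile(res$profile, paste0(stem, "_nsld.txt"))
  if (!is.null(res$parameters)) {
    p <- res$parameters
    to_json(lapply(p[c("D", "D_B", "two_Dc", "D_w", "A", "n_w")],
                   function(v) list(value = v$value, se = v$se)),
            paste0(stem, "_parameters.json"))
  }
  to_json(res$log, paste0(stem, "_runlog.json"))
  invisible(NULL)
}

#' @export
print.condition_result <- function(x, ...) {
  cat("<condition_result>", x$label, "- phase:", x$phase_class, "\n")
  if (!is.null(x$parameters)) print(x$parameters)
  else cat("  parameters unavailable:", x$reason, "\n")
  invisible(x)
}

#' Tabulate parameters across conditions
#'
#' Builds the condition-by-parameter table (rows D, D_B, 2D_c, D_w, n_w;
#' one column per condition) with \code{"value +/- se"} cells rounded to
#' 0.1 and empty cells where a condition's parameters were unavailable
#' (non-lamellar phase or too few Bragg orders).
#'
#' @param results list of \code{"condition_result"} objects from
#'   \code{\link{run_condition}}.
#' @return A data frame with rownames \code{D}, \code{D_B}, \code{two_Dc},
#'   \code{D_w}, \code{n_w}; attribute \code{"phase_class"} holds each
#'   condition's class.
#' @export
run_report <- function(results) {
  if (inherits(results, "condition_result")) results <- list(results)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "condition_result")))
  rows <- c("D", "D_B", "two_Dc", "D_w", "n_w")
  fmt <- function(v) sprintf("%.1f ± %.1f", v$value, v$se)
  cols <- lapply(results, function(res) {
    out <- setNames(rep("", length(rows)), rows)
    if (!is.null(res$parameters)) {
      for (r in rows) out[r] <- fmt(res$parameters[[r]])
    } else if (res$phase_class %in% c("lamellar", "coexisting_lamellar") &&
               length(res$assignment$lattices)) {
      # lattice constant(s) still known without a full parameter set
      out["D"] <- paste(vapply(res$assignment$lattices, function(l)
        fmt(list(value = l$D, se = l$D_se)), ""), collapse = " / ")
    }
    out
  })
  tab <- as.data.frame(cols, optional = TRUE)
  names(tab) <- vapply(results, `[[`, "", "label")
  attr(tab, "phase_class") <- setNames(
    vapply(results, `[[`, "", "phase_class"), names(tab))
  tab
}

#' Write / read a parameter report
#'
#' \code{write_report_csv} writes the table as CSV;
#' \code{write_report_json} / \code{read_report_json} round-trip the table
#' together with the per-condition phase classes.
#'
#' @param report a data frame from \code{\link{run_report}}.
#' @param path file path.
#' @return The path (writers, invisibly) or the report (reader).
#' @export
write_report_csv <- function(report, path) {
  write.csv(report, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(rows = rownames(report),
         conditions = names(report),
         phase_class = as.list(attr(report, "phase_class")),
         cells = as.list(report)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- as.data.frame(obj$cells, optional = TRUE)
  names(tab) <- obj$conditions
  rownames(tab) <- obj$rows
  attr(tab, "phase_class") <- unlist(obj$phase_class)
  tab
}
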