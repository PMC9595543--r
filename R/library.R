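#' Build the atom library for one sensor type
#'
#' Runs the full two-stage procedure: ICA decomposition and component
#' selection once, then `n_runs` (4) iterations of peak detection, MUSIC
#' refinement and rank-1 convolutional sparse coding (3 atoms per run). The
#' first run uses all selected components; the topographies of the selected
#' components are k-means clustered (k = 3, on unit-normalized absolute
#' topographies) and each subsequent run restricts peak detection to one
#' cluster, forcing the sparse coding to organize around different subsets
#' of events. Runs whose component group yields no candidates are skipped
#' with a message, so the candidate count can fall short of
#' `n_runs * n_atoms_per_run` = 12.
#'
#' @param rec a [sensor_recording()] of ONE sensor type at 200 Hz (raw;
#'   band-passing to `cfg$csc_band` happens internally).
#' @param fwd a [forward_model()].
#' @param cfg a [pipeline_config()].
#' @param seed integer seed; run `r` uses `seed + r` for the sparse-coding
#'   initialization.
#' @return An object of class `"atom_library"`: `atoms` (list of scored
#'   `csc_atom`s), `info` (tibble: id, run, atom, score, n_events, theta
#'   values, selected flag), `stage1_events`, `component_set`, `sensor_type`.
#' @export
build_library <- function(rec, fwd, cfg = pipeline_config(), seed = 1) {
  stopifnot(inherits(rec, "sensor_recording"))
  rec_bp <- bandpass(rec, cfg$csc_band[1], cfg$csc_band[2])
  cs <- ica_decompose(rec_bp, cfg$n_ica, seed = seed)
  cs <- score_components(cs, fwd, cfg)
  if (!any(cs$selected)) {
    abort("no candidates: no ICA component passed selection",
          class = "megspike_no_candidates")
  }
  sel <- which(cs$selected)

  # topography clustering for runs 2..n_runs: k-means on unit-normalized
  # absolute topographies, one cluster per subsequent run
  k_sub <- min(cfg$n_runs - 1L, length(sel))
  groups <- vector("list", cfg$n_runs)
  groups[[1]] <- sel
  if (k_sub >= 1L && length(sel) >= 1L) {
    topo <- abs(cs$topographies[, sel, drop = FALSE])
    topo <- sweep(topo, 2L, sqrt(colSums(topo^2)), "/")
    if (length(sel) > k_sub) {
      set.seed(seed)
      km <- kmeans(t(topo), centers = k_sub, nstart = 5)
      for (g in seq_len(k_sub)) groups[[g + 1L]] <- sel[km$cluster == g]
    } else {
      for (g in seq_along(sel)) groups[[g + 1L]] <- sel[g]
    }
  }

  atoms <- list()
  info <- NULL
  stage1 <- NULL
  for (r in seq_len(cfg$n_runs)) {
    grp <- groups[[r]]
    if (is.null(grp) || !length(grp)) {
      message(sprintf("library run %d: empty component group, skipped", r))
      next
    }
    run_res <- tryCatch({
      pk <- detect_component_peaks(cs, cfg, components = grp)
      ev <- refine_peaks(pk, rec_bp, fwd, cfg)
      ep <- extract_epochs(rec_bp, ev, cfg$epoch_len)
      fit <- fit_rank1_csc(ep, K = cfg$n_atoms_per_run,
                           lambda = cfg$lambda_reg, n_iter = cfg$csc_n_iter,
                           seed = seed + r, atom_len_s = cfg$atom_len,
                           tol = cfg$csc_tol)
      list(pk = pk, ev = ev, ep = ep, fit = fit)
    }, megspike_no_candidates = function(e) NULL)
    if (is.null(run_res)) {
      message(sprintf("library run %d: no candidate events, skipped", r))
      next
    }
    if (r == 1L) stage1 <- run_res$ev
    for (a in run_res$fit$atoms) {
      a <- assign_events(a, cfg)
      a <- score_atom(a, run_res$ep, fwd, cfg)
      a$run <- r
      a$id <- sprintf("%s_r%d_a%d", rec$sensor_type[1], r, a$k)
      atoms <- c(atoms, list(a))
      info <- rbind(info, data.frame(
        id = a$id, run = r, atom = a$k, score = a$score,
        n_events = NROW(a$assigned_events),
        peak_theta = run_res$pk$theta,
        mad_theta = a$theta_used, stringsAsFactors = FALSE))
    }
  }
  if (!length(atoms)) {
    abort("no candidates: every library run failed",
          class = "megspike_no_candidates")
  }
  lib <- structure(
    list(atoms = atoms, info = as_tibble(info), stage1_events = stage1,
         component_set = cs, sensor_type = rec$sensor_type[1]),
    class = "atom_library")
  select_atoms(lib, cfg$exclude_atoms)
}

#' Select library atoms by the mean + 1 SD score rule
#'
#' An atom is selected when its score exceeds the mean plus one standard
#' deviation of the candidate score distribution. An exclusion list of atom
#' ids (emulating visual review) forces atoms out of the selection.
#'
#' @param lib an `atom_library` (or a merged library, see
#'   [merge_libraries()]).
#' @param exclude character vector of atom ids to force out.
#' @return The library with `info$selected` updated.
#' @export
select_atoms <- function(lib, exclude = character(0)) {
  stopifnot(inherits(lib, "atom_library"))
  sc <- lib$info$score
  thr <- mean(sc) + sd(sc)
  if (is.na(thr)) thr <- -Inf               # single candidate: select it
  lib$info$selected <- sc > thr & !(lib$info$id %in% exclude)
  lib
}

#' Merge per-sensor-type atom libraries
#'
#' Gradiometer and magnetometer atoms are independent contributions; their
#' candidates are pooled and the mean + 1 SD selection is recomputed across
#' the pooled score distribution.
#'
#' @param ... `atom_library` objects.
#' @param exclude passed to [select_atoms()].
#' @return A merged `atom_library` (`sensor_type = "merged"`).
#' @export
merge_libraries <- function(..., exclude = character(0)) {
  libs <- list(...)
  stopifnot(length(libs) >= 1, all(vapply(libs, inherits, logical(1),
                                          "atom_library")))
  lib <- structure(
    list(atoms = do.call(c, lapply(libs, `[[`, "atoms")),
         info = do.call(rbind, lapply(libs, `[[`, "info")),
         stage1_events = NULL, component_set = NULL,
         sensor_type = "merged"),
    class = "atom_library")
  select_atoms(lib, exclude)
}

#' @export
print.atom_library <- function(x, ...) {
  cat(sprintf("<atom_library: %s> %d candidate atoms, %d selected\n",
              x$sensor_type, nrow(x$info), sum(x$info$selected)))
  print(x$info)
  invisible(x)
}

#' Tidy an atom library into a tibble of candidates
#'
#' @param x an `atom_library`.
#' @param ... unused.
#' @return The per-candidate tibble (id, run, atom index, score, event
#'   count, adaptive thresholds, selected flag).
#' @export
tidy.atom_library <- function(x, ...) x$info

#' One-row library summary
#'
#' @param x an `atom_library`.
#' @param ... unused.
#' @export
glance.atom_library <- function(x, ...) {
  tibble(sensor_type = x$sensor_type,
         n_candidates = nrow(x$info),
         n_selected = sum(x$info$selected),
         mean_score = mean(x$info$score),
         sd_score = sd(x$info$score),
         total_events = sum(x$info$n_events))
}
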