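#' Read and write tracking CSV
#'
#' The canonical exchange format is a per-frame CSV with header
#' `trial_id, fish_id, t_s, x_mm, y_mm, valid` (one row per frame per fish,
#' UTF-8, decimal point; an optional `genotype` column is preserved).
#' Column-mapping lets tracker exports with different header names be read
#' without converting the file.
#'
#' @param path File path.
#' @param arena Arena the coordinates refer to.
#' @param fps Nominal frame rate of the recording.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's header names, e.g. `c(t_s = "time", x_mm = "X")`.
#' @return A named list of [trajectory()] objects, keyed
#'   `"<trial_id>/<fish_id>"`, samples sorted by time.
#' @export
read_tracking <- function(path, arena, fps = 25, column_map = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(df))
        zt_abort(paste0("mapped column not in file: ", column_map[[nm]]))
      names(df)[names(df) == column_map[[nm]]] <- nm
    }
  }
  need <- c("trial_id", "fish_id", "t_s", "x_mm", "y_mm", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss))
    zt_abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  if (nrow(df) == 0) zt_abort("no samples in tracking file")
  bad <- !is.finite(df$t_s) | (!is.finite(df$x_mm) & df$valid != 0)
  if (any(bad))
    rlang::warn(paste0("malformed rows at line(s): ",
                       paste(head(which(bad) + 1L, 10), collapse = ", ")))
  df <- df[!bad, , drop = FALSE]
  has_gt <- "genotype" %in% names(df)
  keys <- paste(df$trial_id, df$fish_id, sep = "/")
  out <- lapply(split(seq_len(nrow(df)), keys), function(idx) {
    d <- df[idx, , drop = FALSE]
    d <- d[order(d$t_s), , drop = FALSE]
    valid <- as.logical(d$valid)
    # out-of-arena points are kept but invalidated, with a warning
    oob <- valid & !arena_contains(arena, d$x_mm, d$y_mm, tol = 1e-6)
    if (any(oob)) {
      rlang::warn(sprintf("fish %s: %d out-of-arena point(s) flagged invalid",
                          d$fish_id[1], sum(oob)))
      valid[oob] <- FALSE
    }
    trajectory(d$fish_id[1],
               tibble::tibble(t = d$t_s, x = d$x_mm, y = d$y_mm,
                              valid = valid),
               fps = fps, arena = arena,
               genotype = if (has_gt) d$genotype[1] else "WT")
  })
  out
}

#' @rdname read_tracking
#' @param trajectories A [trajectory()] or list of them.
#' @param trial_id Trial identifier written to the file.
#' @export
write_tracking <- function(trajectories, path, trial_id = "trial1") {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  rows <- purrr::map_dfr(trajectories, function(tr) {
    tibble::tibble(trial_id = trial_id, fish_id = tr$fish_id,
                   t_s = tr$samples$t, x_mm = tr$samples$x,
                   y_mm = tr$samples$y,
                   valid = as.integer(tr$samples$valid),
                   genotype = tr$genotype)
  })
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read pre-binned activity records
#'
#' Supports tracker exports that provide only per-bin distances (columns
#' `fish_id`, `bin_start_s`, `distance_mm`). The resulting profiles carry no
#' underlying trajectory, so trajectory-requiring metrics (thigmotaxis, SPI,
#' shoaling) refuse them.
#'
#' @param path CSV path.
#' @return Named list of `activity_profile` objects (one per fish).
#' @export
read_binned <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("fish_id", "bin_start_s", "distance_mm")
  if (!all(need %in% names(df)))
    zt_abort("binned file needs columns fish_id, bin_start_s, distance_mm")
  out <- lapply(split(df, df$fish_id), function(d) {
    d <- d[order(d$bin_start_s), , drop = FALSE]
    w <- diff(d$bin_start_s)
    if (length(w) && max(w) - min(w) > 1e-9)
      zt_abort("inconsistent bin widths")
    bin_s <- if (length(w)) w[1] else 30
    structure(list(fish_id = d$fish_id[1],
                   genotype = if ("genotype" %in% names(d)) d$genotype[1] else "WT",
                   bins = tibble::tibble(bin_start_s = d$bin_start_s,
                                         distance_mm = d$distance_mm,
                                         n_frames = NA_integer_,
                                         frac_missing = 0, flagged = FALSE),
                   window = c(min(d$bin_start_s),
                              max(d$bin_start_s) + bin_s),
                   bin_s = bin_s,
                   mean_activity = mean(d$distance_mm),
                   binned_only = TRUE),
              class = "activity_profile")
  })
  out
}
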