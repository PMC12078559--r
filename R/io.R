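#' Read 2D trajectories from a spot-table export
#'
#' Reads the delimited spot tables exported by particle-tracking software
#' (one row per detection with track id, x, y and frame and/or time
#' columns). The delimiter (comma or tab) is sniffed from the header line,
#' `#`-prefixed comment lines are skipped, and common column-name variants
#' (`TRACK_ID`/`track_id`/`track`, `POSITION_X`/`x`, `POSITION_T`/`time`,
#' `FRAME`/`frame`) are recognized; pass `column_map` to override. Rows are
#' grouped by track id and sorted by time; tracks with fewer than two points
#' are dropped with a message.
#'
#' @param path Path to the delimited text file (header row required).
#' @param column_map Optional named list/character vector mapping the roles
#'   `track_id`, `x`, `y`, and `time` or `frame` to column names in the
#'   file.
#' @param frame_interval Seconds per frame, used when only a frame column is
#'   present (default 0.2).
#' @return A list of [trajectory()] objects.
#' @export
read_trajectories <- function(path, column_map = NULL, frame_interval = 0.2) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 50L)
  header <- lines[!startsWith(lines, "#")][1L]
  if (is.na(header)) stop("no header row found")
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)

  find_col <- function(role, candidates) {
    if (!is.null(column_map) && role %in% names(column_map))
      return(as.character(column_map[[role]]))
    hit <- candidates[candidates %in% names(tab)]
    if (length(hit)) hit[1L] else NA_character_
  }
  cid <- find_col("track_id", c("track_id", "TRACK_ID", "track", "Track"))
  cx <- find_col("x", c("x", "X", "POSITION_X", "x_um"))
  cy <- find_col("y", c("y", "Y", "POSITION_Y", "y_um"))
  ct <- find_col("time", c("time", "t", "POSITION_T", "time_s"))
  cf <- find_col("frame", c("frame", "FRAME"))
  missing <- c(track_id = cid, x = cx, y = cy)[is.na(c(cid, cx, cy))]
  if (length(missing) || (is.na(ct) && is.na(cf)))
    stop("cannot resolve required columns: ",
         paste(c(names(missing), if (is.na(ct) && is.na(cf)) "time/frame"),
               collapse = ", "))
  for (cc in c(cid, cx, cy, ct, cf)) {
    if (!is.na(cc) && !cc %in% names(tab))
      stop("column not in file: ", cc)
  }
  times <- if (!is.na(ct)) as.numeric(tab[[ct]])
           else as.numeric(tab[[cf]]) * frame_interval
  ids <- as.character(tab[[cid]])
  split_idx <- split(seq_len(nrow(tab)), ids)
  dropped <- 0L
  out <- list()
  for (id in names(split_idx)) {
    idx <- split_idx[[id]][order(times[split_idx[[id]]])]
    if (length(idx) < 2L) { dropped <- dropped + 1L; next }
    out[[length(out) + 1L]] <-
      trajectory(id, times[idx], cbind(tab[[cx]][idx], tab[[cy]][idx]),
                 frame_interval = frame_interval)
  }
  if (dropped > 0L)
    message(dropped, " track(s) with < 2 points dropped")
  out
}

.provenance_header <- function(seed = NULL, config = NULL) {
  h <- sprintf("# photoswim %s | written %s",
               as.character(utils::packageVersion("photoswim")),
               format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (!is.null(config)) {
    cfg <- paste(names(config), unname(vapply(config, function(v)
      paste(format(v), collapse = " "), character(1))),
      sep = "=", collapse = "; ")
    h <- c(h, paste0("# config: ", cfg,
                     sprintf(" | hash=%08x", sum(utf8ToInt(cfg) *
                                                 seq_along(utf8ToInt(cfg))) %% 2^31)))
  }
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %d", seed))
  h
}

#' Write a data frame as CSV with a provenance header
#'
#' Every output file carries `#`-prefixed comment lines recording the
#' package version, a hash of the configuration echo, and the seed, so a
#' rerun with the same configuration is traceable. [read_trajectories()]
#' and `read.csv(..., comment.char = "#")` skip these lines.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Optional integer seed to record.
#' @param config Optional named list echoed (and hashed) into the header.
#' @return `path`, invisibly.
#' @export
write_csv_provenance <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.provenance_header(seed = seed, config = config), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write trajectories in the spot-table dialect
#'
#' Long-format CSV (`track_id,frame,time,x,y`) in the same dialect
#' [read_trajectories()] consumes, with a provenance header.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param path Output path.
#' @inheritParams write_csv_provenance
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path, seed = NULL, config = NULL) {
  rows <- lapply(trajectories, function(tr) {
    data.frame(track_id = tr$track_id,
               frame = round(tr$times / tr$frame_interval),
               time = tr$times,
               x = tr$positions[, 1L], y = tr$positions[, 2L])
  })
  write_csv_provenance(do.call(rbind, rows), path, seed = seed,
                       config = config)
}

#' Write MSD curves in long format
#'
#' @param curves List of `"msd_curve"` objects.
#' @param path Output path.
#' @inheritParams write_csv_provenance
#' @return `path`, invisibly.
#' @export
write_msd_curves <- function(curves, path, seed = NULL, config = NULL) {
  rows <- lapply(curves, function(cu)
    data.frame(track_id = cu$track_id, tau = cu$lags, msd = cu$values))
  write_csv_provenance(do.call(rbind, rows), path, seed = seed,
                       config = config)
}

# ---- command-line dispatch -------------------------------------------------

.parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

.cli_usage <- function() {
  cat("usage: photoswim <subcommand> [--flag value ...]\n",
      "subcommands:\n",
      "  simulate  --f 0.125 [--horizon 300] [--out series.csv]\n",
      "  sweep     [--frequencies 0.0125,0.125,0.625] [--horizon 300] [--out summary.csv]\n",
      "  ablate    [--frequencies ...] [--horizon 300] [--out summary.csv]\n",
      "  msd       --in spots.csv [--truncate-fraction 0.2] [--fit-fraction 0.2]\n",
      "            [--top-k 20] [--roi-center x,y] [--direction-override d] [--out d_table.csv]\n",
      "  swim      --in interface.csv [--f 0.02] [--out steps.csv]\n",
      "  cycle     --a 20 --ds 20 --dr 10\n",
      "  modes     [--tmin 25] [--tmax 70] [--out modes.csv]\n",
      "  synth     --kind brownian [--n-particles 50] [--n-steps 100] [--seed 1] --out spots.csv\n",
      sep = "")
}

#' Dispatch a command-line invocation
#'
#' Thin command-line binding over the package functions, callable as
#' `cli_dispatch(commandArgs(trailingOnly = TRUE))` from an Rscript wrapper
#' (one ships in `inst/cli/photoswim.R`). Deterministic stages accept
#' `--seed` for provenance logging only.
#'
#' @param args Character vector of arguments: a subcommand followed by
#'   `--flag value` pairs.
#' @return Integer exit status, invisibly (0 on success).
#' @export
cli_dispatch <- function(args) {
  if (length(args) == 0L) {
    .cli_usage()
    return(invisible(1L))
  }
  sub <- args[1L]
  flags <- tryCatch(.parse_flags(args[-1L]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags))
    .cli_usage()
    return(invisible(1L))
  }
  num <- function(key, default = NULL) {
    if (!is.null(flags[[key]])) as.numeric(flags[[key]]) else default
  }
  nums <- function(key, default) {
    if (!is.null(flags[[key]]))
      as.numeric(strsplit(flags[[key]], ",")[[1L]]) else default
  }
  seed <- as.integer(num("seed", 1L))

  status <- tryCatch({
    d <- switch(sub,
      cycle = {
        est <- cycle_estimate(num("a"), num("ds"), num("dr"))
        print(est)
        0L
      },
      simulate = {
        defs <- default_model_params()
        f <- num("f", defs$frequencies[2L])
        horizon <- num("horizon", defs$horizon)
        s <- simulate_condensate(defs$params, schedule_for_frequency(f, horizon),
                                 m_L0 = defs$m_L0, horizon = horizon)
        out <- flags[["out"]] %||% "series.csv"
        stride <- max(1L, as.integer(num("stride", 1L)))
        keep <- seq(1L, nrow(s), by = stride)
        write_csv_provenance(as.data.frame(s)[keep, ], out, seed = seed,
                             config = list(f = f, horizon = horizon))
        cat("wrote", out, "\n")
        0L
      },
      sweep = ,
      ablate = {
        defs <- default_model_params()
        fs <- nums("frequencies", defs$frequencies)
        horizon <- num("horizon", defs$horizon)
        tabf <- if (sub == "sweep") frequency_sweep else ablation_compare
        tab <- tabf(defs$params, fs, horizon, m_L0 = defs$m_L0)
        print(tab)
        if (!is.null(flags[["out"]]))
          write_csv_provenance(tab, flags[["out"]], seed = seed,
                               config = list(frequencies = fs, horizon = horizon))
        0L
      },
      msd = {
        trajs <- read_trajectories(flags[["in"]])
        curves <- lapply(trajs, compute_msd_fft)
        ests <- lapply(curves, fit_diffusion,
                       truncate_fraction = num("truncate-fraction", 0.2),
                       fit_fraction = num("fit-fraction", 0.2))
        dirs <- if (!is.null(flags[["direction-override"]]))
          rep(flags[["direction-override"]], length(ests))
        else classify_direction(trajs, roi_center = nums("roi-center", NULL))
        ests <- signed_estimates(ests, dirs)
        top <- select_top(ests, k = as.integer(num("top-k", 20L)))
        tab <- estimates_table(top)
        print(tab)
        if (!is.null(flags[["out"]]))
          write_csv_provenance(tab, flags[["out"]], seed = seed)
        0L
      },
      swim = {
        tab <- utils::read.csv(flags[["in"]], comment.char = "#")
        ds <- displacement_series(cbind(tab$x_um, tab$y_um), tab$time_s)
        print(ds)
        if (!is.null(flags[["out"]]))
          write_csv_provenance(as.data.frame(ds), flags[["out"]], seed = seed)
        0L
      },
      modes = {
        grid <- seq(num("tmin", 25), num("tmax", 70), by = 1)
        tab <- mode_table(variant_fixtures(), grid)
        print(tab[tab$mode != "none", ])
        if (!is.null(flags[["out"]]))
          write_csv_provenance(tab, flags[["out"]], seed = seed)
        0L
      },
      synth = {
        spec <- generator_spec(kind = flags[["kind"]],
                               n_particles = as.integer(num("n-particles", 50L)),
                               n_steps = as.integer(num("n-steps", 100L)),
                               D_true = num("d-true", 0.5),
                               v_true = num("v-true", 1),
                               seed = seed)
        gen <- switch(spec$kind,
                      brownian = gen_brownian,
                      ballistic = gen_ballistic,
                      radial_spread = ,
                      radial_collapse = gen_radial)
        if (is.null(gen)) stop("synth only writes trajectory kinds")
        write_trajectories(gen(spec), flags[["out"]] %||% "spots.csv",
                           seed = seed, config = unclass(spec)[
                             c("kind", "n_particles", "n_steps", "D_true",
                               "v_true", "noise_sigma")])
        cat("wrote", flags[["out"]] %||% "spots.csv", "\n")
        0L
      },
      {
        message("unknown subcommand: ", sub)
        .cli_usage()
        1L
      })
    d
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
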