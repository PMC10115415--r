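# Delimited-text dialects for the assay observations. Every file starts with
# `# key=value` comment lines (metadata, generator parameters) followed by a
# header row.

write_commented_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    keep <- !vapply(meta, is.null, logical(1))
    writeLines(sprintf("#%s=%s", names(meta)[keep],
                       vapply(meta[keep], format, character(1))), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_commented_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      val <- suppressWarnings(as.numeric(kv[2]))
      meta[[trimws(kv[1])]] <- if (is.na(val)) trimws(kv[2]) else val
    }
  }
  df <- tryCatch(
    utils::read.csv(text = paste(lines[!is_meta], collapse = "\n")),
    error = function(e) stop("malformed CSV in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  list(data = df, meta = meta)
}

#' Read and write titration series CSV files
#'
#' Dialect: comment lines `#key=value`, then columns `l_total_uM`,
#' `shift_ppm` and optionally `p_total_uM`. A scalar observed-species total
#' may instead travel in the `#p_total_uM` metadata line.
#'
#' @param series a [titration_series()].
#' @param path file path.
#' @return `read_titration_csv()` returns a [titration_series()];
#'   `write_titration_csv()` returns `path` invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  df <- data.frame(l_total_uM = series$l_totals,
                   shift_ppm = series$shifts,
                   p_total_uM = series$p_total)
  meta <- c(list(delta_free_ppm = series$delta_free), series$meta)
  write_commented_csv(df, path, meta[!duplicated(names(meta))])
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  parsed <- read_commented_csv(path)
  df <- parsed$data
  need <- c("l_total_uM", "shift_ppm")
  if (!all(need %in% names(df)))
    stop(path, " is not a titration CSV (needs columns ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  p_total <- if ("p_total_uM" %in% names(df)) df$p_total_uM
             else parsed$meta$p_total_uM
  if (is.null(p_total))
    stop(path, " has neither a p_total_uM column nor metadata", call. = FALSE)
  dfree <- parsed$meta$delta_free_ppm
  titration_series(p_total, df$l_total_uM, df$shift_ppm,
                   delta_free = if (is.null(dfree))
                     df$shift_ppm[which.min(df$l_total_uM)] else dfree,
                   meta = parsed$meta)
}

#' Read and write ITC thermogram CSV files
#'
#' Dialect: metadata lines `#cell_uM=`, `#syringe_uM=`, `#V0_uL=` (plus any
#' generator metadata), then columns `inj_vol_uL`, `heat_ucal`.
#'
#' @param tg an [itc_thermogram()].
#' @param path file path.
#' @return `read_itc_csv()` returns an [itc_thermogram()];
#'   `write_itc_csv()` returns `path` invisibly.
#' @export
write_itc_csv <- function(tg, path) {
  stopifnot(inherits(tg, "itc_thermogram"))
  meta <- c(list(cell_uM = tg$cell_uM, syringe_uM = tg$syringe_uM,
                 V0_uL = tg$cell_vol_uL), tg$meta)
  write_commented_csv(data.frame(inj_vol_uL = tg$inj_vol_uL,
                                 heat_ucal = tg$heats),
                      path, meta[!duplicated(names(meta))])
}

#' @rdname write_itc_csv
#' @export
read_itc_csv <- function(path) {
  parsed <- read_commented_csv(path)
  df <- parsed$data
  need <- c("inj_vol_uL", "heat_ucal")
  if (!all(need %in% names(df)))
    stop(path, " is not an ITC CSV (needs columns ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  for (k in c("cell_uM", "syringe_uM", "V0_uL"))
    if (is.null(parsed$meta[[k]]))
      stop(path, " lacks required metadata line #", k, "=", call. = FALSE)
  itc_thermogram(parsed$meta$V0_uL, parsed$meta$cell_uM,
                 parsed$meta$syringe_uM, df$inj_vol_uL, df$heat_ucal,
                 meta = parsed$meta)
}

#' Read and write progress-curve CSV files
#'
#' Dialect: metadata lines `#enzyme_uM=`, `#s_cis0_uM=`, then columns
#' `time_s`, `signal`. One file holds one curve.
#'
#' @param curve a [progress_curve()].
#' @param path file path.
#' @return `read_progress_csv()` returns a [progress_curve()];
#'   `write_progress_csv()` returns `path` invisibly.
#' @export
write_progress_csv <- function(curve, path) {
  stopifnot(inherits(curve, "progress_curve"))
  meta <- c(list(enzyme_uM = curve$enzyme_uM, s_cis0_uM = curve$s_cis0_uM),
            curve$meta)
  write_commented_csv(data.frame(time_s = curve$times,
                                 signal = curve$signal),
                      path, meta[!duplicated(names(meta))])
}

#' @rdname write_progress_csv
#' @export
read_progress_csv <- function(path) {
  parsed <- read_commented_csv(path)
  df <- parsed$data
  need <- c("time_s", "signal")
  if (!all(need %in% names(df)))
    stop(path, " is not a progress-curve CSV (needs columns ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  for (k in c("enzyme_uM", "s_cis0_uM"))
    if (is.null(parsed$meta[[k]]))
      stop(path, " lacks required metadata line #", k, "=", call. = FALSE)
  progress_curve(parsed$meta$enzyme_uM, parsed$meta$s_cis0_uM,
                 df$time_s, df$signal, meta = parsed$meta)
}
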