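#' Fit an exponential-phase growth rate to one plug series
#'
#' Ordinary least squares of ln(area) on day, restricted to the window of
#' exponential growth. The slope is the growth rate in day^-1. The maximum
#' colony area is taken over the full observed series, not only the window,
#' since colonies keep expanding after the exponential phase.
#'
#' @param day,area numeric vectors of equal length; `day` strictly
#'   increasing, `area` > 0 (mm^2).
#' @param window numeric length-2: inclusive day range fitted. The default
#'   covers the first few days where growth is exponential.
#' @return one-row data.frame: rate, intercept, window_lo, window_hi,
#'   n_points, r_squared, max_area.
#' @export
fit_growth <- function(day, area, window = c(0, 4)) {
  stopifnot(length(day) == length(area), length(window) == 2)
  if (is.unsorted(day, strictly = TRUE)) {
    stop("validation error: days must be strictly increasing", call. = FALSE)
  }
  if (any(area <= 0)) {
    stop("validation error: non-positive area", call. = FALSE)
  }
  inw <- day >= window[1] & day <= window[2]
  if (sum(inw) < 3) {
    stop("insufficient data: need >= 3 in-window points, have ", sum(inw),
         call. = FALSE)
  }
  x <- day[inw]
  y <- log(area[inw])
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  data.frame(
    rate = slope, intercept = intercept,
    window_lo = window[1], window_hi = window[2],
    n_points = sum(inw), r_squared = r2,
    max_area = max(area)
  )
}

#' Fit growth rates for every plug in a plate table
#'
#' Applies [fit_growth()] per (plate, plug). Excluded plates are skipped and
#' carried in the `skipped` attribute; plugs with too few in-window points
#' are reported, not silently dropped.
#'
#' @param plates long plate data.frame ([read_plates()] /
#'   [simulate_experiment()]).
#' @param window inclusive day window for the log-linear fit.
#' @return data.frame of fits with plate metadata (plate_id, plug_index,
#'   treatment, focal, opponent, ph, replicate) plus [fit_growth()] columns.
#'   Attribute `skipped` lists excluded or unfittable plugs with reasons.
#' @export
fit_growth_all <- function(plates, window = c(0, 4)) {
  split_key <- paste(plates$plate_id, plates$plug_index, sep = "\r")
  groups <- split(seq_len(nrow(plates)), split_key)
  fits <- vector("list", length(groups))
  skipped <- list()
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    meta <- plates[idx[1], c("plate_id", "plug_index", "treatment", "focal",
                             "opponent", "ph", "replicate"), drop = FALSE]
    if (isTRUE(plates$excluded[idx[1]])) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        meta, reason = paste0("excluded: ",
                              plates$exclusion_reason[idx[1]]))
      next
    }
    ord <- idx[order(plates$day[idx])]
    fit <- tryCatch(
      fit_growth(plates$day[ord], plates$area_mm2[ord], window),
      error = function(e) conditionMessage(e)
    )
    if (is.character(fit)) {
      skipped[[length(skipped) + 1L]] <- data.frame(meta, reason = fit)
    } else {
      fits[[g]] <- cbind(meta, fit)
    }
  }
  out <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    NULL
  out
}

#' Keep one randomly chosen plug per self-vs-self plate
#'
#' SvS plates carry two identical plugs; downstream analyses use only one,
#' chosen at random, to avoid pseudo-replication. The choice is reproducible
#' under the seed.
#'
#' @param svs_fits growth-fit rows for SvS plates (two plugs per plate).
#' @param seed integer seed for the plug choice.
#' @return `svs_fits` subset to one row per plate.
#' @export
select_svs_plug <- function(svs_fits, seed = 1L) {
  stopifnot(all(svs_fits$treatment == "SvS"))
  counts <- table(svs_fits$plate_id)
  if (any(counts != 2)) {
    stop("structure error: SvS plate(s) without exactly 2 plugs: ",
         paste(names(counts)[counts != 2], collapse = ", "), call. = FALSE)
  }
  plate_ids <- sort(unique(svs_fits$plate_id))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  chosen_plug <- sample(1:2, length(plate_ids), replace = TRUE)
  keep_key <- paste(plate_ids, chosen_plug)
  out <- svs_fits[paste(svs_fits$plate_id, svs_fits$plug_index) %in%
                    keep_key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write growth fits to CSV
#'
#' @param fits output of [fit_growth_all()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_growth_fits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE, na = "")
  invisible(path)
}
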