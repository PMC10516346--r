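#' Effect of competition (EoC) per competition plug
#'
#' EoC is the ratio of a plug's growth response on a competition plate to the
#' mean response of its species' pH-matched self-vs-self (SvS) controls
#' (after random plug selection). EoC = 1 means competition had no effect;
#' the log ratio is carried alongside for modeling.
#'
#' @param competition_fits growth-fit rows for competition plugs.
#' @param svs_fits SvS growth-fit rows, one plug per plate
#'   ([select_svs_plug()]).
#' @param response "growth_rate" (the `rate` column) or "colony_size"
#'   (`max_area`).
#' @return data.frame: plate_id, plug_index, focal, opponent, ph, replicate,
#'   response, eoc, log_eoc.
#' @export
compute_eoc <- function(competition_fits, svs_fits,
                        response = c("growth_rate", "colony_size")) {
  response <- match.arg(response)
  col <- if (response == "growth_rate") "rate" else "max_area"
  base_key <- paste(svs_fits$focal, svs_fits$ph)
  baselines <- tapply(svs_fits[[col]], base_key, mean)
  comp_key <- paste(competition_fits$focal, competition_fits$ph)
  unresolved <- setdiff(unique(comp_key), names(baselines))
  if (length(unresolved)) {
    stop("unresolved baseline: no SvS fits for (focal, pH): ",
         paste(unresolved, collapse = "; "), call. = FALSE)
  }
  base <- baselines[comp_key]
  if (any(base <= 0)) {
    stop("domain error: non-positive SvS baseline mean for: ",
         paste(unique(comp_key[base <= 0]), collapse = "; "), call. = FALSE)
  }
  eoc <- competition_fits[[col]] / unname(base)
  data.frame(
    plate_id = competition_fits$plate_id,
    plug_index = competition_fits$plug_index,
    focal = competition_fits$focal,
    opponent = competition_fits$opponent,
    ph = competition_fits$ph,
    replicate = competition_fits$replicate,
    response = response,
    eoc = eoc,
    log_eoc = log(eoc),
    stringsAsFactors = FALSE
  )
}

#' Growth-based distance matrix between species at one pH
#'
#' The trait-based competitor of patristic distance: entry (i, j) is the
#' absolute difference of the two species' mean SvS responses at the given
#' pH, e.g. |mean rate_i - mean rate_j|.
#'
#' @param svs_fits SvS growth-fit rows, one plug per plate.
#' @param ph pH level to subset on.
#' @param response "growth_rate" or "colony_size".
#' @return a [dist_matrix()] of the matching kind, tagged with `ph`.
#' @export
growth_distance <- function(svs_fits, ph,
                            response = c("growth_rate", "colony_size")) {
  response <- match.arg(response)
  col <- if (response == "growth_rate") "rate" else "max_area"
  sub <- svs_fits[svs_fits$ph == ph, , drop = FALSE]
  species <- sort(unique(svs_fits$focal))
  means <- tapply(sub[[col]], sub$focal, mean)
  absent <- setdiff(species, names(means))
  if (length(absent)) {
    stop("species with no SvS data at pH ", ph, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  m <- abs(outer(means[species], means[species], "-"))
  dimnames(m) <- list(species, species)
  kind <- if (response == "growth_rate") "growth_rate" else "colony_size"
  dist_matrix(m, kind = kind, ph = ph)
}

#' Default index-of-antagonism scoring table
#'
#' Wicklow–Hirschfield-style point values for the physical interaction at
#' the contact zone. The overgrowing fungus always scores strictly more than
#' the fungus it overtakes; symmetric outcomes score equally. Any published
#' variant can be supplied instead as a data.frame with the same columns.
#'
#' @return data.frame: category, focal_score, opponent_score. For
#'   overgrowth categories the "focal" is the overgrower.
#' @export
default_ioa_table <- function() {
  data.frame(
    category = c("intermingling", "deadlock_distance", "deadlock_contact",
                 "overgrowth_partial", "overgrowth_complete"),
    focal_score = c(2L, 1L, 2L, 4L, 5L),
    opponent_score = c(2L, 1L, 2L, 1L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Score contact-zone observations with an antagonism point table
#'
#' @param observations data.frame: plate_id, focal, opponent, ph, category.
#'   For overgrowth categories, `focal` is the overgrowing fungus.
#' @param scoring_table category-to-points table; see [default_ioa_table()].
#' @return data.frame: plate_id, focal, opponent, ph, category, focal_score,
#'   opponent_score.
#' @export
score_ioa <- function(observations, scoring_table = default_ioa_table()) {
  i <- match(observations$category, scoring_table$category)
  if (anyNA(i)) {
    stop("vocabulary error: unknown categories: ",
         paste(unique(observations$category[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    observations[c("plate_id", "focal", "opponent", "ph", "category")],
    focal_score = scoring_table$focal_score[i],
    opponent_score = scoring_table$opponent_score[i],
    stringsAsFactors = FALSE
  )
}
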