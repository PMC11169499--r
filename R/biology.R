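#' Competency window
#'
#' Age interval (days post-release) during which a larva can settle;
#' broadcast-spawning *Acropora* larvae are taken as competent from 4 to 28
#' days after spawning.
#'
#' @param min_age,max_age Window bounds, days; `0 < min_age < max_age`.
#' @return An object of class `competency_window`.
#' @export
competency_window <- function(min_age = 4, max_age = 28) {
  if (!(min_age > 0 && min_age < max_age))
    stop("need 0 < min_age < max_age", call. = FALSE)
  structure(list(min_age = min_age, max_age = max_age),
            class = "competency_window")
}

#' Daily mortality model
#'
#' Cohort-level daily thinning: each dispersal day, a fixed fraction of the
#' still-active larvae is removed uniformly at random.
#'
#' @param daily_rate Fraction removed per day, in `[0, 1)`; default 0.40.
#' @param seed Integer seed; each day's draw is seeded by `(seed, day)` so
#'   replays are reproducible stage by stage.
#' @return An object of class `mortality_model`.
#' @export
mortality_model <- function(daily_rate = 0.40, seed = 1L) {
  if (daily_rate < 0 || daily_rate >= 1)
    stop("daily_rate must be in [0, 1)", call. = FALSE)
  structure(list(daily_rate = daily_rate, seed = as.integer(seed)),
            class = "mortality_model")
}

#' Build a spawning-night release schedule
#'
#' One virtual larva per site per 3-minute slot from 20:00 to 23:00 inclusive
#' (61 slots), released at a uniform random point inside the site polygon at
#' 2.25 m depth. Points are drawn by rejection sampling from the site's
#' bounding box, testing containment against the site's hexagons, so they are
#' uniform over the (possibly multi-part) polygon.
#'
#' @param sites A `site_set` from [make_site_polygons()].
#' @param night_start Clock origin of the night, hours on the simulation
#'   clock (00:00 of the spawning date); releases run `night_start + 20 h`
#'   to `night_start + 23 h`.
#' @param seed Integer seed.
#' @param night_id Identifier stored with the events.
#' @param release_depth Release depth, metres (default 2.25).
#' @param cadence_min Release cadence, minutes (default 3).
#' @param window_hours Start/end of the nightly window, hours after
#'   `night_start` (default `c(20, 23)`, inclusive).
#' @return An object of class `release_schedule`: a data frame of events
#'   (`particle_id, site_id, x, y, z, time, night_id`).
#' @export
build_release_schedule <- function(sites, night_start = 0, seed = 1L,
                                   night_id = 1L, release_depth = 2.25,
                                   cadence_min = 3,
                                   window_hours = c(20, 23)) {
  if (is.null(sites$sites) || nrow(sites$sites) == 0L) {
    ev <- data.frame(particle_id = integer(0), site_id = integer(0),
                     x = numeric(0), y = numeric(0), z = numeric(0),
                     time = numeric(0), night_id = integer(0))
    return(structure(list(events = ev, night_id = night_id, seed = seed),
                     class = "release_schedule"))
  }
  slots <- seq(window_hours[1] * 60, window_hours[2] * 60, by = cadence_min)
  n_slot <- length(slots)
  map <- sites$map
  events <- with_local_seed(mix_seed(seed, "release", night_id), {
    out <- vector("list", nrow(sites$sites))
    for (s in seq_len(nrow(sites$sites))) {
      ids <- sites$members[[s]]
      if (length(ids) == 0L)
        stop("site ", sites$sites$site_id[s], " has no hexagons", call. = FALSE)
      hx <- map$hexes[match(ids, map$hexes$id), ]
      bb <- c(min(hx$x) - map$size, max(hx$x) + map$size,
              min(hx$y) - map$size, max(hx$y) + map$size)
      if (bb[1] >= bb[2] || bb[3] >= bb[4])
        stop("site ", sites$sites$site_id[s], " has degenerate geometry",
             call. = FALSE)
      xs <- ys <- numeric(n_slot)
      got <- 0L
      while (got < n_slot) {
        m <- (n_slot - got) * 4L
        cx <- runif(m, bb[1], bb[2]); cy <- runif(m, bb[3], bb[4])
        hit <- which(locate_hex(map, cx, cy) %in% ids)
        take <- head(hit, n_slot - got)
        if (length(take)) {
          xs[got + seq_along(take)] <- cx[take]
          ys[got + seq_along(take)] <- cy[take]
          got <- got + length(take)
        }
      }
      out[[s]] <- data.frame(
        site_id = sites$sites$site_id[s], x = xs, y = ys,
        z = release_depth, time = night_start + slots / 60)
      out[[s]]
    }
    do.call(rbind, out)
  })
  events <- events[order(events$time, events$site_id), ]
  events <- data.frame(particle_id = seq_len(nrow(events)), events,
                       night_id = night_id, row.names = NULL)
  structure(list(events = events, night_id = night_id, seed = seed),
            class = "release_schedule")
}

#' @export
print.release_schedule <- function(x, ...) {
  cat("<release_schedule> night ", x$night_id, ": ", nrow(x$events),
      " events over ", length(unique(x$events$site_id)), " sites\n", sep = "")
  invisible(x)
}

#' Apply one day of mortality thinning
#'
#' Removes `round(daily_rate * n_active)` particles, chosen uniformly without
#' replacement, from the active set; the draw is seeded by the model seed and
#' the day index, so day-by-day replays are reproducible.
#'
#' @param active_ids Vector of active particle ids.
#' @param model A [mortality_model()].
#' @param day_index Dispersal day (>= 1).
#' @return The surviving ids; the removed ids are attached as
#'   `attr(, "removed")`.
#' @export
apply_daily_mortality <- function(active_ids, model, day_index) {
  stopifnot(inherits(model, "mortality_model"), day_index >= 1)
  n <- length(active_ids)
  n_remove <- round(model$daily_rate * n)
  if (n_remove == 0L) {
    out <- active_ids
    attr(out, "removed") <- active_ids[0]
    return(out)
  }
  removed <- with_local_seed(mix_seed(model$seed, "mortality", day_index),
                             sample(active_ids, n_remove))
  out <- setdiff(active_ids, removed)
  attr(out, "removed") <- removed
  out
}

#' Settlement detection at recorded positions
#'
#' A larva settles instantly on the first reef site polygon its recorded
#' position falls inside while its age is within the competency window; the
#' natal site counts (self-recruitment). Containment is resolved through the
#' hexagon lattice, which is boundary-inclusive up to the deterministic
#' nearest-centre assignment of boundary points.
#'
#' @param x,y Recorded positions (vectorized).
#' @param age_days Particle ages, days.
#' @param window A [competency_window()].
#' @param sites A `site_set`.
#' @return Integer site ids, `NA` where the larva does not settle.
#' @export
detect_settlement <- function(x, y, age_days, window, sites) {
  sid <- locate_site(sites, x, y)
  sid[age_days < window$min_age | age_days > window$max_age] <- NA_integer_
  sid
}

#' Settlement hook for the tracker
#'
#' Wraps [detect_settlement()] as a [track()] status hook: at each record
#' point, active larvae inside a site polygon during their competency window
#' flip to `settled` with the containing site recorded.
#'
#' @param sites A `site_set`.
#' @param window A [competency_window()].
#' @return A hook `function(active_df, time_hours)`.
#' @export
make_settlement_hook <- function(sites, window = competency_window()) {
  function(df, t_now) {
    sid <- detect_settlement(df$x, df$y, df$age_days, window, sites)
    hit <- which(!is.na(sid))
    if (!length(hit)) return(NULL)
    quick_df(list(particle_id = df$particle_id[hit],
                  status = rep("settled", length(hit)),
                  settle_site = sid[hit]))
  }
}

#' Combined settlement + nightly-cohort mortality hook
#'
#' Settlement is checked at every record point; at each whole day after the
#' night's release-window start (i.e. at `night_ref + d * 24 h`), the cohort
#' is thinned with [apply_daily_mortality()] *before* that record's
#' settlement check, matching daily removal of a fixed fraction of the
#' remaining larvae.
#'
#' @param sites A `site_set`.
#' @param window A [competency_window()].
#' @param mortality A [mortality_model()] (or `NULL` for none).
#' @param night_ref Reference time of the cohort (hours): the start of the
#'   release window.
#' @return A hook `function(active_df, time_hours)`.
#' @export
make_biology_hook <- function(sites, window = competency_window(),
                              mortality = NULL, night_ref = 0) {
  last_day <- 0L
  function(df, t_now) {
    out <- NULL
    if (!is.null(mortality)) {
      day <- floor((t_now - night_ref) / 24 + 1e-9)
      if (day > last_day) {
        dead_ids <- integer(0)
        for (d in (last_day + 1L):day) {
          surv <- apply_daily_mortality(df$particle_id, mortality, d)
          dead_ids <- c(dead_ids, attr(surv, "removed"))
          df <- df[df$particle_id %in% surv, , drop = FALSE]
        }
        last_day <<- day
        if (length(dead_ids))
          out <- quick_df(list(particle_id = dead_ids,
                               status = rep("dead", length(dead_ids)),
                               settle_site = rep(NA_integer_,
                                                 length(dead_ids))))
      }
    }
    sid <- detect_settlement(df$x, df$y, df$age_days, window, sites)
    hit <- which(!is.na(sid))
    if (length(hit))
      out <- rbind(out, quick_df(list(particle_id = df$particle_id[hit],
                                      status = rep("settled", length(hit)),
                                      settle_site = sid[hit])))
    out
  }
}

#' Settlement records from tracked trajectories
#'
#' @param trajectories A `trajectories` object.
#' @param night_id Night identifier to attach.
#' @return Data frame `particle_id, source_site, sink_site, settle_time,
#'   night_id` with one row per settled larva (first-hit settlement
#'   guarantees at most one record per particle).
#' @export
settlement_records <- function(trajectories, night_id = 1L) {
  i <- which(trajectories$status_label == "settled")
  data.frame(particle_id = trajectories$particles$particle_id[i],
             source_site = trajectories$particles$source_site[i],
             sink_site = trajectories$settle_site[i],
             settle_time = trajectories$status_time[i],
             release_time = trajectories$particles$release_time[i],
             night_id = rep(night_id, length(i)))
}
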