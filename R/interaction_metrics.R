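#' Construct a behaviour-mapping congregate session
#'
#' Raw primitives recorded for one observation session in one spatial
#' study unit: the unit area, the crowd totals at the start and end of
#' the interaction window, and one row per person present giving the
#' size of the congregate group that person belongs to and the time (in
#' minutes, capped by the 60-minute observation window) that group spent
#' congregating. Solitary visitors are included with group size 1.
#'
#' @param unit_id study-unit number.
#' @param S unit site area in m^2 (must exceed 1, so the log10 area
#'   normalizer is positive).
#' @param A_start,A_end total crowd counts at interaction start and end;
#'   each person is assumed to appear in the space only once.
#' @param persons data.frame with columns `B` (congregate group size,
#'   >= 1) and `T` (congregate time, minutes in \[1, 60\]), one row per
#'   person present.
#' @param N total number of people present; defaults to `nrow(persons)`.
#' @return object of class `congregate_session`.
#' @export
congregate_session <- function(unit_id, S, A_start, A_end, persons,
                               N = nrow(persons)) {
  stopifnot(is.data.frame(persons), all(c("B", "T") %in% names(persons)))
  if (S <= 1)
    stop("unit area S must exceed 1 m^2 (log10(S) must be positive)",
         call. = FALSE)
  if (A_start < 0 || A_end < 0) stop("crowd counts must be nonnegative", call. = FALSE)
  if (N < 1) stop("N must be at least 1", call. = FALSE)
  if (any(persons$T < 1 | persons$T > 60))
    stop("congregate times must lie in [1, 60] minutes; cap observations ",
         "at the 60-minute window upstream", call. = FALSE)
  if (any(persons$B < 1) || any(persons$B > N))
    stop("group sizes B must lie in [1, N]", call. = FALSE)
  structure(list(unit_id = as.integer(unit_id), S = as.numeric(S),
                 A_start = as.numeric(A_start), A_end = as.numeric(A_end),
                 persons = persons, N = as.integer(N)),
            class = "congregate_session")
}

#' Average crowd total over the interaction window
#'
#' The session-level average crowd size: the mean of the crowd totals at
#' the start and end of the interaction.
#'
#' @param A_start,A_end crowd totals at interaction start and end.
#' @return `(A_start + A_end) / 2`.
#' @export
average_crowd_size <- function(A_start, A_end) {
  if (any(A_start < 0) || any(A_end < 0))
    stop("crowd counts must be nonnegative", call. = FALSE)
  if (any(A_start + A_end == 0))
    stop("degenerate session: no crowd observed at either endpoint, ",
         "congregate index undefined", call. = FALSE)
  (A_start + A_end) / 2
}

#' Crowds-congregate index of a session
#'
#' The area-normalized congregate index
#' \deqn{R = \frac{\sum_{i=1}^{N} (B_i / A)\,\ln T_i}{N \log_{10} S}}
#' where the sum runs over all N people present, \eqn{B_i} is the size
#' of person i's congregate group, \eqn{T_i} the group's congregate time
#' in minutes, \eqn{A} the average crowd total over the window, and
#' \eqn{S} the unit area in m^2. Natural log for times, base-10 log for
#' area. Nonnegative whenever all `T >= 1` and `S > 1`.
#'
#' @param session a [congregate_session].
#' @return the index R (nonnegative real).
#' @export
congregate_index <- function(session) {
  stopifnot(inherits(session, "congregate_session"))
  A <- average_crowd_size(session$A_start, session$A_end)
  sum((session$persons$B / A) * log(session$persons$T)) /
    (session$N * log10(session$S))
}

#' Engagement-with-the-park score
#'
#' Mean of the three 1-7 questionnaire items: participation intensity,
#' preference for the space, and daily visit frequency.
#'
#' @param item_participation,item_preference,item_frequency integer
#'   scores in 1-7 (vectors allowed).
#' @return numeric score(s) in \[1, 7\].
#' @export
engagement_score <- function(item_participation, item_preference, item_frequency) {
  items <- cbind(item_participation, item_preference, item_frequency)
  if (any(items < 1 | items > 7 | items != round(items)))
    stop("questionnaire items must be integers in 1..7", call. = FALSE)
  rowMeans(items)
}

#' Summarize social-interaction levels by space type
#'
#' Groups sessions and engagement responses by their unit's space type
#' and reports mean and standard deviation of the congregate index and
#' engagement score per type, each with a descending-by-mean rank.
#' Types with no data are omitted with a warning.
#'
#' @param sessions list of [congregate_session] objects.
#' @param responses data.frame with columns `unit_id`, `item1`, `item2`,
#'   `item3`.
#' @param units unit inventory data.frame ([load_spatial_units()]).
#' @return data.frame with one row per space type: `space_type`,
#'   `n_sessions`, `congregate_mean`, `congregate_sd`, `congregate_rank`,
#'   `n_responses`, `engagement_mean`, `engagement_sd`, `engagement_rank`.
#' @export
summarize_by_space_type <- function(sessions, responses, units) {
  type_of <- function(uid) {
    ix <- match(uid, units$unit_id)
    if (anyNA(ix)) stop("unresolvable unit_id: ",
                        paste(unique(uid[is.na(ix)]), collapse = ", "),
                        call. = FALSE)
    units$space_type[ix]
  }
  r_vals <- vapply(sessions, congregate_index, numeric(1))
  r_type <- type_of(vapply(sessions, `[[`, integer(1), "unit_id"))
  e_vals <- engagement_score(responses$item1, responses$item2, responses$item3)
  e_type <- type_of(responses$unit_id)

  types <- unique(c(r_type, e_type))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  out <- data.frame(
    space_type = types,
    n_sessions = vapply(types, function(t) sum(r_type == t), integer(1)),
    congregate_mean = vapply(types, function(t) mean(r_vals[r_type == t]), numeric(1)),
    congregate_sd = vapply(types, function(t) sd0(r_vals[r_type == t]), numeric(1)),
    n_responses = vapply(types, function(t) sum(e_type == t), integer(1)),
    engagement_mean = vapply(types, function(t) mean(e_vals[e_type == t]), numeric(1)),
    engagement_sd = vapply(types, function(t) sd0(e_vals[e_type == t]), numeric(1)),
    row.names = NULL)
  empty <- setdiff(c("fitness_equipment", "path", "sports_court"), types)
  if (length(empty))
    warning("space type(s) with no data omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out$congregate_rank <- rank(-out$congregate_mean, ties.method = "first")
  out$engagement_rank <- rank(-out$engagement_mean, ties.method = "first")
  out[order(out$congregate_rank), ]
}

#' Write / read congregate sessions as a pair of CSV files
#'
#' `sessions.csv` holds one row per session (`session_id`, `unit_id`,
#' `S_m2`, `A_start`, `A_end`); `session_persons.csv` holds the
#' long-format person rows (`session_id`, `B`, `T_min`).
#'
#' @param sessions list of [congregate_session] objects.
#' @param dir directory the two CSVs are written into.
#' @return `dir`, invisibly.
#' @export
write_sessions_csv <- function(sessions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  head_df <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    data.frame(session_id = i, unit_id = s$unit_id, S_m2 = s$S,
               A_start = s$A_start, A_end = s$A_end)
  }))
  pers_df <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    p <- sessions[[i]]$persons
    data.frame(session_id = i, B = p$B, T_min = p$T)
  }))
  utils::write.csv(head_df, file.path(dir, "sessions.csv"), row.names = FALSE)
  utils::write.csv(pers_df, file.path(dir, "session_persons.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sessions_csv
#' @export
read_sessions_csv <- function(dir) {
  head_df <- utils::read.csv(file.path(dir, "sessions.csv"))
  pers_df <- utils::read.csv(file.path(dir, "session_persons.csv"))
  lapply(head_df$session_id, function(i) {
    h <- head_df[head_df$session_id == i, ]
    p <- pers_df[pers_df$session_id == i, c("B", "T_min")]
    names(p) <- c("B", "T")
    rownames(p) <- NULL
    congregate_session(h$unit_id, h$S_m2, h$A_start, h$A_end, p)
  })
}
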