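#' Pair homologous control spectra between two sessions
#'
#' Homologous spectra are acquisitions of the same physical zone (same
#' `zone_id`, i.e. same specimen and zone index) made in different
#' experimental sessions. Control specimens measured in every session
#' provide these pairs; no manifest flag is needed, any zone present in both
#' sessions qualifies.
#'
#' @param matrix An `xrf_landmarks` object.
#' @param session Session to align.
#' @param reference_session Session used as the morphological reference.
#' @return A data frame with columns `zone_id`, `row_session`,
#'   `row_reference` (row indices into `matrix$values`). Zones lacking a
#'   partner are excluded with a message.
#' @export
pair_homologous <- function(matrix, session, reference_session) {
  stopifnot(inherits(matrix, "xrf_landmarks"))
  meta <- matrix$meta
  for (s in c(session, reference_session)) {
    if (!s %in% meta$session) stopf("session '%s' absent from matrix", s)
  }
  in_s <- which(meta$session == session)
  in_r <- which(meta$session == reference_session)
  if (session == reference_session) in_r <- in_s
  common <- intersect(meta$zone_id[in_s], meta$zone_id[in_r])
  if (length(common) == 0L) {
    stopf("no homologous spectra between '%s' and '%s'",
          session, reference_session)
  }
  dropped <- setdiff(union(meta$zone_id[in_s], meta$zone_id[in_r]), common)
  dropped <- dropped[dropped %in% meta$zone_id[in_s] |
                       dropped %in% meta$zone_id[in_r]]
  # only zones that *should* pair (present in one of the two sessions but
  # not the other) are worth reporting; singleton study zones are expected
  n_multi <- table(meta$zone_id)[dropped]
  really_dropped <- names(n_multi)[n_multi > 1L]
  if (length(really_dropped)) {
    message(sprintf("pair_homologous: excluded zone(s) without partner: %s",
                    paste(really_dropped, collapse = ", ")))
  }
  data.frame(zone_id = common,
             row_session = in_s[match(common, meta$zone_id[in_s])],
             row_reference = in_r[match(common, meta$zone_id[in_r])],
             stringsAsFactors = FALSE)
}

#' Mean morphological difference between a session and the reference
#'
#' For each landmark, the average over homologous pairs of
#' `value[session] - value[reference]`. Subtracting this mean difference
#' from every spectrum of the session removes the setup-specific spectral
#' morphology it shares.
#'
#' @param matrix An `xrf_landmarks` object.
#' @param pairs Pairing table from [pair_homologous()], or `NULL` to compute
#'   it from `session` / `reference_session`.
#' @param session,reference_session Session labels (required when `pairs`
#'   is `NULL`; otherwise recovered from the pair rows).
#' @return A `xrf_batch_delta` object: `session`, `reference_session`,
#'   `delta` (831-vector), `n_pairs`.
#' @export
compute_mean_delta <- function(matrix, pairs = NULL, session = NULL,
                               reference_session = NULL) {
  stopifnot(inherits(matrix, "xrf_landmarks"))
  if (is.null(pairs)) {
    if (is.null(session) || is.null(reference_session)) {
      stopf("give either a pairs table or session + reference_session")
    }
    pairs <- pair_homologous(matrix, session, reference_session)
  }
  if (nrow(pairs) < 1L) stopf("no homologous pairs")
  if (is.null(session)) {
    session <- unique(matrix$meta$session[pairs$row_session])
  }
  if (is.null(reference_session)) {
    reference_session <- unique(matrix$meta$session[pairs$row_reference])
  }
  diffs <- matrix$values[pairs$row_session, , drop = FALSE] -
    matrix$values[pairs$row_reference, , drop = FALSE]
  structure(list(session = session[1L],
                 reference_session = reference_session[1L],
                 delta = colMeans(diffs), n_pairs = nrow(pairs)),
            class = "xrf_batch_delta")
}

#' @export
print.xrf_batch_delta <- function(x, ...) {
  cat(sprintf("<xrf_batch_delta> %s -> %s: %d pairs, |delta| in [%.3g, %.3g]\n",
              x$session, x$reference_session, x$n_pairs,
              min(abs(x$delta)), max(abs(x$delta))))
  invisible(x)
}

#' Realign one session onto the reference session
#'
#' Subtracts the mean homologous difference landmark-wise from every row of
#' the session; all other rows are untouched. Within-session differences are
#' preserved exactly (a common curve is removed from every row).
#'
#' @param matrix An `xrf_landmarks` object.
#' @param delta A `xrf_batch_delta` from [compute_mean_delta()].
#' @return The realigned `xrf_landmarks`; the session is recorded in
#'   `aligned_sessions`.
#' @export
apply_realignment <- function(matrix, delta) {
  stopifnot(inherits(matrix, "xrf_landmarks"),
            inherits(delta, "xrf_batch_delta"))
  if (length(delta$delta) != ncol(matrix$values)) {
    stopf("delta length %d does not match matrix grid (%d landmarks)",
          length(delta$delta), ncol(matrix$values))
  }
  rows <- which(matrix$meta$session == delta$session)
  if (length(rows) == 0L) {
    warnf("session '%s' absent from matrix; returned unchanged", delta$session)
    return(matrix)
  }
  matrix$values[rows, ] <- sweep(matrix$values[rows, , drop = FALSE], 2L,
                                 delta$delta, `-`)
  matrix$aligned_sessions <- union(matrix$aligned_sessions, delta$session)
  matrix
}

#' Align every non-reference session onto the reference
#'
#' Convenience wrapper: for each non-reference session, pair the homologous
#' control spectra, compute the mean difference and subtract it. Each
#' session is aligned directly to the reference (no chaining).
#'
#' @param matrix An `xrf_landmarks` object.
#' @param reference_session The reference session label.
#' @return A list: `matrix` (aligned) and `deltas` (one `xrf_batch_delta`
#'   per non-reference session).
#' @export
align_sessions <- function(matrix, reference_session) {
  stopifnot(inherits(matrix, "xrf_landmarks"))
  sessions <- setdiff(unique(matrix$meta$session), reference_session)
  if (!reference_session %in% matrix$meta$session) {
    stopf("reference session '%s' absent from matrix", reference_session)
  }
  deltas <- list()
  for (s in sessions) {
    d <- compute_mean_delta(matrix, session = s,
                            reference_session = reference_session)
    matrix <- apply_realignment(matrix, d)
    deltas[[s]] <- d
  }
  matrix$aligned_sessions <- union(matrix$aligned_sessions, reference_session)
  list(matrix = matrix, deltas = deltas)
}

#' Collapse control pseudo-replicates measured in several sessions
#'
#' Rows sharing a `zone_id` (the same physical zone re-acquired in different
#' sessions) are replaced by their landmark-wise arithmetic mean so that no
#' zone is over-represented downstream; their `session` becomes `"merged"`.
#' Single-session zones pass through unchanged.
#'
#' @param matrix An `xrf_landmarks` object, normally already realigned.
#' @return The averaged `xrf_landmarks` (one row per analysed zone).
#' @export
average_pseudoreplicates <- function(matrix) {
  stopifnot(inherits(matrix, "xrf_landmarks"))
  n_sessions <- length(unique(matrix$meta$session))
  if (n_sessions > 1L && length(matrix$aligned_sessions) == 0L) {
    warnf("averaging a multi-session matrix that was never realigned")
  }
  ids <- unique(matrix$meta$zone_id)
  rows <- lapply(ids, function(z) which(matrix$meta$zone_id == z))
  values <- do.call(rbind, lapply(rows, function(r) {
    colMeans(matrix$values[r, , drop = FALSE])
  }))
  meta <- matrix$meta[vapply(rows, `[`, 1L, 1L), , drop = FALSE]
  merged <- vapply(rows, length, 1L) > 1L
  meta$session[merged] <- "merged"
  rownames(meta) <- NULL
  out <- landmark_matrix(values, meta)
  out$aligned_sessions <- matrix$aligned_sessions
  out$averaged <- TRUE
  out
}
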