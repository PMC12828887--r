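#' Build a pseudopopulation across sessions
#'
#' Pools units recorded in different sessions into one population by
#' aligning trials across sessions. Within each session, valid pairs at the
#' target N-backs are split into the four conditions (novel/exact,
#' repeat/exact, novel/lure, lure). Lure pairs are sorted ascending by
#' dissimilarity and aligned across sessions by rank; exact pairs are put in
#' a seeded random order (consistent with every exact pair having
#' dissimilarity 0). Every session is trimmed to the minimum per-condition
#' pair count by seeded random ablation, so all units share the same pair
#' axis.
#'
#' Alignment permutes trials only; no spike count is edited.
#'
#' @param sessions List of `session_recording` objects (e.g.
#'   `simulate_study(cfg)$sessions`).
#' @param region Optional region filter; sessions from other regions are
#'   dropped.
#' @param target_nbacks Integer vector of N-backs to keep (default: all).
#' @param seed Integer seed for the ablation and exact-pair ordering.
#' @return An object of class `pseudopopulation`: list with `region`,
#'   `unit_ids` (session:unit labels), `blocks` (named list of
#'   unit x pair x bin arrays for `novel_exact`, `repeat_exact`,
#'   `novel_lure`, `lure`), `lure_d` (ascending; per-rank mean of session
#'   dissimilarities), `time_bins_ms`, and `n_sessions`.
#' @export
build_pseudopopulation <- function(sessions, region = NULL,
                                   target_nbacks = NULL, seed = 1L) {
  stopifnot(length(sessions) >= 1L)
  if (!is.null(region)) {
    sessions <- Filter(function(s) identical(s$region, region), sessions)
    if (!length(sessions)) stop("no session in region ", region, call. = FALSE)
  }
  set.seed(as.integer(seed))

  per_session <- list()
  for (s in sessions) {
    tr <- s$trials
    keep <- tr$valid & tr$condition != "filler"
    if (!is.null(target_nbacks)) keep <- keep & tr$n_back %in% target_nbacks
    tr <- tr[keep, , drop = FALSE]
    split_cond <- function(cond) tr[tr$condition == cond, , drop = FALSE]
    ne1 <- split_cond("novel_exact"); re2 <- split_cond("repeat_exact")
    nl1 <- split_cond("novel_lure");  lu2 <- split_cond("lure")
    ## keep only pairs with both presentations completed
    e_pairs <- intersect(ne1$pair_id, re2$pair_id)
    l_pairs <- intersect(nl1$pair_id, lu2$pair_id)
    if (!length(e_pairs) || !length(l_pairs)) {
      warning("session ", s$session_id,
              " has an empty condition at the target n-backs; dropped",
              call. = FALSE)
      next
    }
    per_session[[length(per_session) + 1L]] <- list(
      session = s,
      exact = data.frame(
        pair_id = e_pairs,
        t_novel = ne1$trial_id[match(e_pairs, ne1$pair_id)],
        t_repeat = re2$trial_id[match(e_pairs, re2$pair_id)]),
      lure = data.frame(
        pair_id = l_pairs,
        t_novel = nl1$trial_id[match(l_pairs, nl1$pair_id)],
        t_lure = lu2$trial_id[match(l_pairs, lu2$pair_id)],
        d = lu2$d[match(l_pairs, lu2$pair_id)]))
  }
  if (!length(per_session)) stop("no usable session", call. = FALSE)

  n_exact <- min(vapply(per_session, function(x) nrow(x$exact), integer(1)))
  n_lure <- min(vapply(per_session, function(x) nrow(x$lure), integer(1)))

  blocks <- list(novel_exact = list(), repeat_exact = list(),
                 novel_lure = list(), lure = list())
  lure_d_mat <- matrix(NA_real_, nrow = length(per_session), ncol = n_lure)
  unit_ids <- character(0)

  for (k in seq_along(per_session)) {
    ps <- per_session[[k]]
    s <- ps$session
    ## seeded random ablation down to the shortest session, then ordering:
    ## exact pairs randomly (d = 0), lure pairs ascending by d
    e_keep <- ps$exact[sample.int(nrow(ps$exact), n_exact), , drop = FALSE]
    l_keep <- ps$lure[sample.int(nrow(ps$lure), n_lure), , drop = FALSE]
    l_keep <- l_keep[order(l_keep$d), , drop = FALSE]
    lure_d_mat[k, ] <- l_keep$d
    blocks$novel_exact[[k]] <- s$counts[, e_keep$t_novel, , drop = FALSE]
    blocks$repeat_exact[[k]] <- s$counts[, e_keep$t_repeat, , drop = FALSE]
    blocks$novel_lure[[k]] <- s$counts[, l_keep$t_novel, , drop = FALSE]
    blocks$lure[[k]] <- s$counts[, l_keep$t_lure, , drop = FALSE]
    unit_ids <- c(unit_ids,
                  paste0(s$session_id, ":", seq_len(dim(s$counts)[1])))
  }

  bind_units <- function(lst) {
    d2 <- dim(lst[[1]])[2]; d3 <- dim(lst[[1]])[3]
    total_u <- sum(vapply(lst, function(a) dim(a)[1], integer(1)))
    out <- array(0L, dim = c(total_u, d2, d3))
    at <- 0L
    for (a in lst) {
      out[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    out
  }

  structure(list(
    region = if (is.null(region)) sessions[[1]]$region else region,
    unit_ids = unit_ids,
    blocks = lapply(blocks, bind_units),
    lure_d = colMeans(lure_d_mat),
    time_bins_ms = sessions[[1]]$time_bins_ms,
    n_sessions = length(per_session)
  ), class = "pseudopopulation")
}

#' @export
print.pseudopopulation <- function(x, ...) {
  cat(sprintf(
    "<pseudopopulation> region=%s: %d units from %d sessions; %d exact pairs, %d lure pairs\n",
    x$region, length(x$unit_ids), x$n_sessions,
    dim(x$blocks$novel_exact)[2], dim(x$blocks$lure)[2]))
  invisible(x)
}
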