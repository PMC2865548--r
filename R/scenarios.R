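## Duplication-scenario parsimony: enumerate the orderings of one local
## (tandem) duplication relative to the two whole-genome duplications,
## compute the minimum gene losses each ordering needs to explain an
## observed repertoire, apply relative-dating feasibility constraints, and
## rank the scenarios.

EVENT_NAMES <- c("LOCAL", "WGD1", "WGD2")

#' Event ordering of one local duplication and two WGDs
#'
#' A valid order contains `LOCAL`, `WGD1` and `WGD2` exactly once with
#' `WGD1` before `WGD2`.
#'
#' @param ... the three event names in order (or a single character vector).
#' @return character vector of class `"event_order"`.
#' @export
event_order <- function(...) {
  ev <- c(...)
  if (!setequal(ev, EVENT_NAMES) || length(ev) != 3L)
    stop("order must contain LOCAL, WGD1, WGD2 exactly once")
  if (which(ev == "WGD1") > which(ev == "WGD2"))
    stop("WGD1 must precede WGD2")
  structure(ev, class = "event_order")
}

#' @rdname event_order
#' @return `all_event_orders`: list of the three valid orderings (local
#'   duplication before, between, and after the two WGDs).
#' @export
all_event_orders <- function() {
  list(event_order("LOCAL", "WGD1", "WGD2"),
       event_order("WGD1", "LOCAL", "WGD2"),
       event_order("WGD1", "WGD2", "LOCAL"))
}

#' Observed gene repertoire on the paralogon chromosomes
#'
#' Per paralogous-chromosome class: the observed gene count and whether
#' that chromosome carries an adjacent same-family pair.
#'
#' @param counts integer vector of gene counts (one per chromosome class).
#' @param adjacent logical vector; `TRUE` where the class carries an
#'   adjacent same-family pair (requires count >= 2).
#' @return list of class `"observed_repertoire"`.
#' @export
observed_repertoire <- function(counts, adjacent = rep(FALSE, length(counts))) {
  stopifnot(length(counts) == length(adjacent), all(counts >= 0))
  if (any(adjacent & counts < 2L))
    stop("adjacency requires at least 2 genes on the chromosome")
  structure(list(counts = as.integer(counts), adjacent = adjacent),
            class = "observed_repertoire")
}

#' @rdname observed_repertoire
#' @return `opioid_observed_repertoire`: the extant opioid prepropeptide
#'   layout - one chromosome with a single gene (enkephalin precursor), one
#'   with the adjacent pair (nociceptin + melanocortin precursors, the
#'   tandem duplicates), one with a single gene (dynorphin precursor), and
#'   one paralogous chromosome with none.
#' @export
opioid_observed_repertoire <- function() {
  observed_repertoire(counts = c(1L, 2L, 1L, 0L),
                      adjacent = c(FALSE, TRUE, FALSE, FALSE))
}

#' Pre-loss repertoire expected under an event ordering
#'
#' Starts from one gene on one chromosome; each WGD doubles every
#' chromosome with its contents; `LOCAL` adds one adjacent copy of a single
#' designated gene (canonically on the first chromosome - the three layouts
#' are symmetric under relabeling, and [min_losses()] minimizes over the
#' chromosome assignment anyway).
#'
#' @param order an [event_order()].
#' @return data.frame with one row per chromosome class: `count`,
#'   `adjacent`.
#' @export
expected_repertoire <- function(order) {
  stopifnot(inherits(order, "event_order"))
  counts <- 1L; adjacent <- FALSE
  for (ev in order) {
    if (ev == "LOCAL") {
      counts[1L] <- counts[1L] + 1L
      adjacent[1L] <- TRUE
    } else {
      counts <- c(counts, counts)
      adjacent <- c(adjacent, adjacent)
    }
  }
  data.frame(count = counts, adjacent = adjacent)
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Minimum gene losses reconciling an ordering with an observed repertoire
#'
#' Exhaustive search over all assignments of expected (pre-loss)
#' chromosomes to observed chromosome classes. An assignment is feasible
#' when every observed count fits under its expected count and every
#' observed adjacent pair maps to a chromosome that carried the tandem
#' pair. The loss count of a feasible assignment is the total number of
#' genes deleted; the minimum over assignments is returned.
#'
#' @param order an [event_order()].
#' @param observed an [observed_repertoire()].
#' @return list with `losses` (integer, `Inf` when structurally
#'   unreachable) and `feasible` (logical).
#' @export
min_losses <- function(order, observed) {
  stopifnot(inherits(order, "event_order"),
            inherits(observed, "observed_repertoire"))
  exp_rep <- expected_repertoire(order)
  ne <- nrow(exp_rep)
  oc <- observed$counts
  oa <- observed$adjacent
  if (length(oc) < ne) {          # unobserved classes are empty chromosomes
    pad <- ne - length(oc)
    oc <- c(oc, rep(0L, pad)); oa <- c(oa, rep(FALSE, pad))
  }
  if (length(oc) > ne) return(list(losses = Inf, feasible = FALSE))
  best <- Inf
  for (perm in .permutations(ne)) {
    ec <- exp_rep$count[perm]; ea <- exp_rep$adjacent[perm]
    if (any(oc > ec)) next
    if (any(oa & !ea)) next
    losses <- sum(ec - oc)
    if (losses < best) best <- losses
  }
  list(losses = best, feasible = is.finite(best))
}

#' Relative-dating constraint on the event order
#'
#' States that one event must precede another, with a provenance note (for
#' instance: the presence of duplicate melanocortin-precursor genes in
#' cyclostomes dates the local duplication before the second genome
#' doubling, under the assumption that cyclostomes diverged before it).
#'
#' @param before,after event names (`LOCAL`, `WGD1`, `WGD2`).
#' @param note free-text provenance recorded in reports.
#' @return list of class `"scenario_constraint"`.
#' @export
scenario_constraint <- function(before, after, note = "") {
  stopifnot(before %in% EVENT_NAMES, after %in% EVENT_NAMES)
  structure(list(before = before, after = after, note = note),
            class = "scenario_constraint")
}

.order_satisfies <- function(order, constraint) {
  which(order == constraint$before) < which(order == constraint$after)
}

#' Rank duplication scenarios by loss parsimony under constraints
#'
#' Computes [min_losses()] for every ordering, flags orderings violating
#' any constraint as infeasible (still reported with their loss count), and
#' sorts feasible orderings by ascending losses (ties keep input order),
#' followed by the infeasible ones.
#'
#' @param orders list of [event_order()]s (default all three).
#' @param observed an [observed_repertoire()].
#' @param constraints list of [scenario_constraint()]s.
#' @return data.frame with `order`, `losses`, `feasible`, `constraint_note`.
#' @export
rank_scenarios <- function(orders = all_event_orders(), observed,
                           constraints = list()) {
  rows <- lapply(seq_along(orders), function(i) {
    ord <- orders[[i]]
    ml <- min_losses(ord, observed)
    viol <- vapply(constraints, function(cn) !.order_satisfies(ord, cn),
                   logical(1))
    notes <- if (any(viol))
      paste(vapply(constraints[viol], function(cn)
        paste0(cn$before, " precedes ", cn$after,
               if (nzchar(cn$note)) paste0(" (", cn$note, ")") else ""),
        character(1)), collapse = "; ")
    else ""
    data.frame(order = paste(ord, collapse = ">"),
               losses = ml$losses,
               feasible = ml$feasible && !any(viol),
               constraint_note = notes,
               input_rank = i,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(!df$feasible, df$losses, df$input_rank), , drop = FALSE]
  df$input_rank <- NULL
  rownames(df) <- NULL
  df
}

#' @rdname rank_scenarios
#' @param ranking output of `rank_scenarios`.
#' @param path output TSV path.
#' @export
write_scenario_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
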