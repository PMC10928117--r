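#' Define a state space for a healthy-working-life multi-state model
#'
#' A state space consists of labelled alive states plus a single absorbing
#' death state (always the last index), together with a mask of permitted
#' instantaneous transitions.
#'
#' @param alive_labels character vector of short labels for the alive states,
#'   in index order.
#' @param allowed logical matrix over (from, to) of dimension
#'   `n_states x n_states` (death last) marking permitted transitions.  The
#'   death row must be all `FALSE` (death is absorbing) and the diagonal is
#'   ignored/forbidden.
#' @param death_label label for the absorbing state.
#' @return An object of class `state_space` with elements `labels`,
#'   `n_states`, `n_alive`, `death` (index of the death state) and `allowed`.
#' @seealso [hwle_states()] for the standard 3- and 5-state presets.
#' @export
state_space <- function(alive_labels, allowed, death_label = "dead") {
  n_alive <- length(alive_labels)
  S <- n_alive + 1L
  if (!is.matrix(allowed) || !identical(dim(allowed), c(S, S)))
    stop("'allowed' must be a ", S, " x ", S, " logical matrix (death last)")
  allowed <- allowed & TRUE  # coerce to logical
  diag(allowed) <- FALSE
  if (any(allowed[S, ]))
    stop("the death state must be absorbing: its row of 'allowed' must be FALSE")
  if (any(!apply(allowed[seq_len(n_alive), , drop = FALSE], 1, any)))
    stop("every alive state needs at least one permitted exit transition")
  structure(
    list(labels = c(alive_labels, death_label),
         n_states = S, n_alive = n_alive, death = S,
         allowed = allowed),
    class = "state_space")
}

#' Standard HWLE state spaces
#'
#' The 3-state model has states 1 = healthy and in work (`HW`),
#' 2 = not healthy and/or not in work (`nHW`), 3 = dead, with permitted
#' transitions 1<->2, 1->3, 2->3.  The 5-state variant distinguishes all four
#' combinations of the binary health and work statuses (1 = `HW`, 2 = healthy
#' not working `HnW`, 3 = not healthy working `nHW_W`, 4 = neither `nHnW`,
#' 5 = dead); all transitions among alive states and from each alive state to
#' death are permitted.
#'
#' @param n_states 3 or 5.
#' @return A [state_space()] object.
#' @examples
#' hwle_states(3)
#' @export
hwle_states <- function(n_states = 3) {
  if (n_states == 3) {
    allowed <- matrix(FALSE, 3, 3)
    allowed[1, 2] <- allowed[2, 1] <- allowed[1, 3] <- allowed[2, 3] <- TRUE
    state_space(c("HW", "nHW"), allowed)
  } else if (n_states == 5) {
    allowed <- matrix(TRUE, 5, 5)
    diag(allowed) <- FALSE
    allowed[5, ] <- FALSE
    state_space(c("HW", "HnW", "nHW_W", "nHnW"), allowed)
  } else {
    stop("n_states must be 3 or 5")
  }
}

#' Permitted transitions of a state space
#'
#' @param space a [state_space()].
#' @return data.frame with columns `from`, `to` (state indices, row-major
#'   order) and `label` such as `"HW-nHW"`.
#' @export
transitions <- function(space) {
  idx <- which(t(space$allowed), arr.ind = TRUE)  # row-major order
  out <- data.frame(from = idx[, 2], to = idx[, 1])
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out$label <- paste(space$labels[out$from], space$labels[out$to], sep = "-")
  out
}

#' Encode binary health/work/vital statuses as model state indices
#'
#' In the 3-state space, alive respondents are state 1 when simultaneously
#' healthy (no limiting long-standing illness) and in paid work, state 2
#' otherwise; the dead are state 3.  In the 5-state space the four
#' health-by-work combinations map to states 1-4 (1 = healthy working,
#' 2 = healthy not working, 3 = not healthy working, 4 = neither) and death
#' to 5.
#'
#' @param healthy,working,dead logical vectors (recycled to common length).
#'   `healthy`/`working` may be `NA` when `dead` is `TRUE`.
#' @param space a [state_space()] created by [hwle_states()].
#' @return integer vector of state indices (`NA` where alive statuses are
#'   missing).
#' @examples
#' encode_states(TRUE, TRUE, FALSE, hwle_states(3))   # 1
#' encode_states(TRUE, FALSE, FALSE, hwle_states(3))  # 2
#' @export
encode_states <- function(healthy, working, dead = FALSE, space = hwle_states(3)) {
  n <- max(length(healthy), length(working), length(dead))
  healthy <- rep_len(as.logical(healthy), n)
  working <- rep_len(as.logical(working), n)
  dead <- rep_len(as.logical(dead), n)
  if (any(dead & (healthy %in% TRUE | working %in% TRUE)))
    stop("'dead' excludes healthy/working statuses")
  if (space$n_alive == 2) {
    out <- ifelse(healthy & working, 1L, 2L)
  } else if (space$n_alive == 4) {
    out <- 1L + (!healthy) * 2L + (!working) * 1L
  } else {
    stop("encode_states() supports the 3- and 5-state presets")
  }
  out[dead] <- space$death
  as.integer(out)
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space:", x$n_alive, "alive state(s) +",
      sQuote(x$labels[x$death]), "\n")
  tr <- transitions(x)
  cat("Permitted transitions:", paste(tr$label, collapse = ", "), "\n")
  invisible(x)
}
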