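#' Declarative-memory parameters
#'
#' Bundles the subsymbolic parameters that govern chunk activation and
#' retrieval in the minimal declarative-memory engine: the base-level decay
#' rate, the instantaneous (logistic) activation-noise scale, and the
#' retrieval threshold.
#'
#' @param d Base-level decay rate, dimensionless, in (0, 1). The ACT-R
#'   default is 0.5.
#' @param s_act Scale of the zero-mean logistic noise added to activations at
#'   retrieval time, dimensionless, `>= 0`. `0` makes retrieval deterministic.
#'   The default 0.23 is the committed calibrated value (see the methods
#'   vignette and `scripts/calibrate.R`).
#' @param tau Retrieval threshold in activation units. A chunk is only
#'   retrievable while its noisy activation exceeds `tau`. The default -5 is
#'   deliberately low so that story facts can always be retrieved: the models'
#'   failures are failures of strategy selection, not of memory for the story.
#'
#' @return A list of class `memory_params`.
#' @export
#' @examples
#' memory_params()
#' memory_params(s_act = 0)
memory_params <- function(d = 0.5, s_act = 0.23, tau = -5) {
  stopifnot(is.numeric(d), length(d) == 1, d > 0, d < 1)
  if (!is.numeric(s_act) || length(s_act) != 1 || s_act < 0) {
    stop("`s_act` must be a single non-negative number", call. = FALSE)
  }
  stopifnot(is.numeric(tau), length(tau) == 1)
  structure(list(d = d, s_act = s_act, tau = tau), class = "memory_params")
}

#' Create a declarative-memory chunk
#'
#' A chunk is a unit of declarative memory: either a story fact or a
#' theory-of-mind strategy, with named symbolic slots, a creation time, a
#' presentation count, and an optional constant activation offset
#' (`base_offset`), used to realize an initialized activation value.
#'
#' @param kind `"fact"` or `"strategy"`.
#' @param slots Named list (or named character vector) of slot values. For a
#'   strategy chunk the single slot is `level` (integer 0..2).
#' @param creation_time Simulated seconds, `>= 0`.
#' @param presentations Presentation count `n >= 1`.
#' @param base_offset Constant added to the base-level term (default 0).
#' @param id Optional identifier; derived from kind and slots if omitted.
#'
#' @return A list of class `chunk`.
#' @export
#' @examples
#' chunk("strategy", list(level = 0), creation_time = 0, base_offset = 6)
chunk <- function(kind, slots, creation_time = 0, presentations = 1,
                  base_offset = 0, id = NULL) {
  kind <- match.arg(kind, c("fact", "strategy"))
  slots <- as.list(slots)
  if (length(slots) == 0 || is.null(names(slots)) || any(names(slots) == "")) {
    stop("`slots` must be a non-empty named list", call. = FALSE)
  }
  stopifnot(presentations >= 1, creation_time >= 0)
  if (is.null(id)) id <- chunk_key(kind, slots)
  structure(
    list(id = id, kind = kind, slots = slots,
         creation_time = as.numeric(creation_time),
         presentations = as.integer(presentations),
         base_offset = as.numeric(base_offset)),
    class = "chunk"
  )
}

# canonical identity key: kind plus sorted slot name=value pairs; two chunks
# with the same key are "identical" and must be merged on encoding
chunk_key <- function(kind, slots) {
  o <- order(names(slots))
  paste0(kind, "|", paste(names(slots)[o], unlist(slots)[o],
                          sep = "=", collapse = ";"))
}

#' Base-level activation of a chunk
#'
#' Computes the optimized-learning form of base-level activation,
#' `B = ln(n / (1 - d)) - d * ln(L) + base_offset`, where `n` is the number
#' of presentations of the chunk and `L = now - creation_time` is its
#' lifetime. Activation grows with frequency of use and decays
#' logarithmically with the time since creation.
#'
#' @param chunk A [chunk()].
#' @param now Current simulated time in seconds; must be strictly greater
#'   than the chunk's creation time.
#' @param params A [memory_params()].
#'
#' @return The noise-free activation (a single real number).
#' @export
#' @examples
#' ch <- chunk("strategy", list(level = 0), creation_time = 0)
#' base_level(ch, now = 1, memory_params())  # ln(2) for n = 1, L = 1, d = 0.5
base_level <- function(chunk, now, params = memory_params()) {
  L <- now - chunk$creation_time
  if (!is.finite(L) || L <= 0) {
    stop("invalid-time: chunk lifetime must be strictly positive", call. = FALSE)
  }
  log(chunk$presentations / (1 - params$d)) - params$d * log(L) +
    chunk$base_offset
}

#' Noisy activation of a chunk
#'
#' Base-level activation plus a zero-mean logistic deviate with scale
#' `params$s_act` (the instantaneous activation noise drawn anew at each
#' retrieval attempt). With `s_act = 0` this equals [base_level()] exactly.
#' Randomness comes from R's global RNG; seed with [set.seed()].
#'
#' @inheritParams base_level
#' @return A single real number.
#' @export
noisy_activation <- function(chunk, now, params = memory_params()) {
  b <- base_level(chunk, now, params)
  if (params$s_act == 0) b else b + stats::rlogis(1, 0, params$s_act)
}

#' Create an empty declarative-memory store
#'
#' The store holds chunks and enforces the merging invariant: two chunks with
#' identical kind and slots never coexist. Internally it keeps parallel
#' vectors for speed; use [dm_chunks()] to extract chunks.
#'
#' @return An object of class `dm_store`.
#' @export
dm_store <- function() {
  structure(
    list(key = character(), kind = character(), slots = list(),
         creation = numeric(), n = integer(), offset = numeric()),
    class = "dm_store"
  )
}

#' @export
print.dm_store <- function(x, ...) {
  cat(sprintf("<dm_store: %d chunks (%d facts, %d strategies)>\n",
              length(x$key), sum(x$kind == "fact"), sum(x$kind == "strategy")))
  invisible(x)
}

#' Number of chunks in a store
#' @param store A [dm_store()].
#' @return Integer count.
#' @export
dm_size <- function(store) length(store$key)

#' Encode a chunk into declarative memory
#'
#' If a chunk with identical kind and slots is already present, the new
#' presentation is merged with it: its presentation count increments by one
#' and its creation time is unchanged. Otherwise the chunk is inserted with
#' one presentation and creation time `now`. The store never grows when a
#' duplicate is encoded.
#'
#' @param store A [dm_store()].
#' @param chunk A [chunk()]. Its `base_offset` is kept on first insertion.
#' @param now Simulated seconds; used as the creation time on first insertion.
#' @return The updated store.
#' @export
#' @examples
#' st <- dm_store()
#' st <- dm_encode(st, chunk("strategy", list(level = 1)), now = 2)
#' st <- dm_encode(st, chunk("strategy", list(level = 1)), now = 4)
#' dm_size(st)  # 1: the two presentations were merged
dm_encode <- function(store, chunk, now) {
  key <- chunk_key(chunk$kind, chunk$slots)
  i <- match(key, store$key)
  if (is.na(i)) {
    store$key <- c(store$key, key)
    store$kind <- c(store$kind, chunk$kind)
    store$slots <- c(store$slots, list(chunk$slots))
    store$creation <- c(store$creation, as.numeric(now))
    store$n <- c(store$n, 1L)
    store$offset <- c(store$offset, chunk$base_offset)
  } else {
    store$n[i] <- store$n[i] + 1L
  }
  store
}

#' Retrieval request
#'
#' A partial description of the chunk wanted: a kind filter and/or slot
#' constraints (slots not mentioned are unconstrained). At least one of the
#' two must be given.
#'
#' @param kind `"fact"`, `"strategy"`, or `NULL` for no kind filter.
#' @param ... Named slot constraints, e.g. `verb = "put"`.
#' @return A list of class `retrieval_request`.
#' @export
#' @examples
#' retrieval_request("fact", verb = "put")
retrieval_request <- function(kind = NULL, ...) {
  constraints <- list(...)
  if (is.null(kind) && length(constraints) == 0) {
    stop("request error: give a kind filter or at least one slot constraint",
         call. = FALSE)
  }
  if (length(constraints) > 0 &&
      (is.null(names(constraints)) || any(names(constraints) == ""))) {
    stop("request error: slot constraints must be named", call. = FALSE)
  }
  structure(list(kind = kind, constraints = constraints),
            class = "retrieval_request")
}

# indices of chunks matching a request
dm_match <- function(store, request) {
  idx <- seq_along(store$key)
  if (!is.null(request$kind)) idx <- idx[store$kind[idx] == request$kind]
  for (nm in names(request$constraints)) {
    want <- request$constraints[[nm]]
    keep <- vapply(store$slots[idx], function(s) {
      !is.null(s[[nm]]) && identical(as.character(s[[nm]]), as.character(want))
    }, logical(1))
    idx <- idx[keep]
  }
  idx
}

# noise-free activations for a set of store indices at time `now`
dm_activation <- function(store, idx, now, params) {
  L <- now - store$creation[idx]
  if (any(L <= 0)) {
    stop("invalid-time: chunk lifetime must be strictly positive", call. = FALSE)
  }
  log(store$n[idx] / (1 - params$d)) - params$d * log(L) + store$offset[idx]
}

#' Retrieve a chunk from declarative memory
#'
#' Among the chunks matching the request, returns the one with the highest
#' noisy activation, provided that activation exceeds the retrieval threshold
#' `params$tau`; otherwise signals retrieval failure by returning `NULL`.
#' With `s_act = 0` the result is the deterministic activation argmax; exact
#' ties are broken in favour of the most recently created chunk.
#'
#' @param store A non-empty [dm_store()].
#' @param request A [retrieval_request()].
#' @param now Simulated seconds.
#' @param params A [memory_params()].
#' @return The retrieved [chunk()], or `NULL` on retrieval failure (no match,
#'   or best noisy activation at or below threshold).
#' @export
dm_retrieve <- function(store, request, now, params = memory_params()) {
  if (!inherits(request, "retrieval_request")) {
    stop("request error: not a retrieval_request", call. = FALSE)
  }
  if (dm_size(store) == 0) stop("store is empty", call. = FALSE)
  idx <- dm_match(store, request)
  if (length(idx) == 0) return(NULL)
  a <- dm_activation(store, idx, now, params)
  if (params$s_act > 0) a <- a + stats::rlogis(length(a), 0, params$s_act)
  best <- max(a)
  if (best <= params$tau) return(NULL)
  cand <- idx[a == best]
  if (length(cand) > 1) cand <- cand[which.max(store$creation[cand])]
  dm_get(store, cand)
}

# materialize store row i as a chunk object
dm_get <- function(store, i) {
  structure(
    list(id = store$key[i], kind = store$kind[i], slots = store$slots[[i]],
         creation_time = store$creation[i], presentations = store$n[i],
         base_offset = store$offset[i]),
    class = "chunk"
  )
}

#' Extract all chunks from a store
#' @param store A [dm_store()].
#' @return A list of [chunk()] objects.
#' @export
dm_chunks <- function(store) lapply(seq_along(store$key), dm_get, store = store)

#' Serialize a memory store to JSON
#'
#' Writes chunk id, kind, slots, creation time, presentation count and base
#' offset, for trace inspection.
#'
#' @param store A [dm_store()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly if written to `path`).
#' @export
dm_to_json <- function(store, path = NULL) {
  rows <- lapply(seq_along(store$key), function(i) {
    list(id = store$key[i], kind = store$kind[i], slots = store$slots[[i]],
         creation_time = store$creation[i], presentations = store$n[i],
         base_offset = store$offset[i])
  })
  js <- jsonlite::toJSON(rows, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
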