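#' Holographic memory item
#'
#' A labelled random unit vector: the atomic operand of the holographic
#' associative memory. All items sharing a memory must have one dimension
#' `n`; vectors are normalized to unit Euclidean length at creation.
#'
#' @param vector Real vector of dimension n (nonzero).
#' @param label Identifier string.
#' @return An object of class `holo_item`.
#' @export
holo_item <- function(vector, label) {
  vector <- as.numeric(vector)
  if (!length(vector) || !all(is.finite(vector))) {
    stop("item vector must be finite and non-empty", call. = FALSE)
  }
  nrm <- sqrt(sum(vector^2))
  if (nrm == 0) stop("item vector must be nonzero", call. = FALSE)
  structure(list(vector = vector / nrm, label = as.character(label)),
            class = "holo_item")
}

#' Random holographic items
#'
#' Draws `count` independent unitary random vectors: unit-length real
#' vectors whose discrete Fourier magnitudes are all 1 (random phase
#' spectrum). For unitary vectors circular correlation with the cue
#' inverts circular convolution exactly, so a single stored binding is
#' recovered perfectly and all recall noise comes from superposition
#' crosstalk and trace degradation — the cleanest substrate for a
#' convolution-based distributed memory. (With plain Gaussian vectors the
#' involution decode carries irreducible self-noise capping single-pair
#' recall correlation near 0.71.)
#'
#' @param count Number of items.
#' @param n Dimension (default 1024).
#' @param labels Optional character vector of labels (default
#'   `item1..itemN`).
#' @return List of [holo_item()] objects.
#' @export
random_items <- function(count, n = 1024, labels = NULL) {
  if (is.null(labels)) labels <- paste0("item", seq_len(count))
  stopifnot(length(labels) == count)
  lapply(seq_len(count), function(i) {
    f <- stats::fft(stats::rnorm(n))
    f <- f / Mod(f)          # unit magnitude, conjugate symmetry preserved
    holo_item(Re(stats::fft(f, inverse = TRUE)) / n, labels[i])
  })
}

#' Impulse identity item
#'
#' The unit impulse `(1, 0, ..., 0)` is the exact identity of circular
#' convolution: binding with it returns the partner unchanged.
#'
#' @param n Dimension.
#' @param label Label (default `"identity"`).
#' @return A [holo_item()].
#' @export
identity_item <- function(n, label = "identity") {
  holo_item(c(1, numeric(n - 1L)), label)
}

#' Holographic trace
#'
#' A distributed memory trace: the superposition of circular-convolution
#' bindings, all of one fixed dimension.
#'
#' @param vector Real vector of dimension n.
#' @param n_bindings Number of bindings superposed in the trace, >= 0.
#' @return An object of class `holo_trace`.
#' @export
holo_trace <- function(vector, n_bindings = 0L) {
  vector <- as.numeric(vector)
  if (!length(vector) || !all(is.finite(vector))) {
    stop("trace vector must be finite and non-empty", call. = FALSE)
  }
  structure(list(vector = vector, n_bindings = as.integer(n_bindings)),
            class = "holo_trace")
}

#' @export
print.holo_trace <- function(x, ...) {
  cat(sprintf("<holo_trace: n = %d, %d binding(s), norm %.4g>\n",
              length(x$vector), x$n_bindings, sqrt(sum(x$vector^2))))
  invisible(x)
}

item_vec <- function(x) {
  if (inherits(x, "holo_item")) x$vector
  else if (inherits(x, "holo_trace")) x$vector
  else as.numeric(x)
}

# circular convolution / correlation via FFT; shift-multiply-sum in O(n log n)
cconv <- function(a, b) {
  Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / length(a)
}
ccorr <- function(a, b) {
  Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / length(a)
}

#' Bind two items by circular convolution
#'
#' Forms the association trace `a (*) b`, where `(*)` is circular
#' convolution — the shift, multiplication and summation that a delay-line
#' substrate can realize directly. Binding is commutative, and for random
#' unit vectors approximately norm-preserving.
#'
#' @param a,b [holo_item()] objects (or traces/vectors) of equal
#'   dimension.
#' @return A [holo_trace()] with `n_bindings = 1`.
#' @export
bind <- function(a, b) {
  va <- item_vec(a)
  vb <- item_vec(b)
  if (length(va) != length(vb)) {
    stop("dimension mismatch: ", length(va), " vs ", length(vb), call. = FALSE)
  }
  holo_trace(cconv(va, vb), n_bindings = 1L)
}

#' Recover a bound partner from a trace
#'
#' Circular correlation of the trace with the cue — the involution-based
#' approximate inverse of [bind()]. When the trace holds `bind(a, b)` and
#' the cue is `a`, the result is a noisy reconstruction of `b`, to be
#' passed through [cleanup()].
#'
#' @param t A [holo_trace()] (or vector).
#' @param cue A [holo_item()] (or vector) of the same dimension.
#' @return Numeric vector: the raw (un-normalized) reconstruction.
#' @export
unbind <- function(t, cue) {
  vt <- item_vec(t)
  vc <- item_vec(cue)
  if (length(vt) != length(vc)) {
    stop("dimension mismatch: ", length(vt), " vs ", length(vc), call. = FALSE)
  }
  ccorr(vc, vt)
}

#' Superpose holographic traces
#'
#' Componentwise vector sum; multiple association traces share one
#' substrate just as multiple holograms can share one film.
#'
#' @param traces Non-empty list of [holo_trace()] objects of equal
#'   dimension.
#' @return A [holo_trace()] whose `n_bindings` is the total.
#' @export
superpose_traces <- function(traces) {
  if (!is.list(traces) || length(traces) == 0L) {
    stop("traces must be a non-empty list", call. = FALSE)
  }
  stopifnot(all(vapply(traces, inherits, logical(1), "holo_trace")))
  ns <- lengths(lapply(traces, `[[`, "vector"))
  if (length(unique(ns)) != 1L) stop("dimension mismatch", call. = FALSE)
  holo_trace(Reduce(`+`, lapply(traces, `[[`, "vector")),
             n_bindings = sum(vapply(traces, `[[`, integer(1), "n_bindings")))
}

#' Content-addressable cleanup dictionary
#'
#' @param items List of [holo_item()] objects with unique labels and one
#'   shared dimension.
#' @param accept_threshold Minimum normalized correlation for a match, in
#'   `[0, 1]` (default 0.15 — above chance-level correlations at
#'   dimensions of 1024 and up, below any plausible signal).
#' @return An object of class `cleanup_dictionary`.
#' @export
cleanup_dictionary <- function(items, accept_threshold = 0.15) {
  if (!is.list(items) || length(items) == 0L) {
    stop("items must be a non-empty list", call. = FALSE)
  }
  stopifnot(all(vapply(items, inherits, logical(1), "holo_item")))
  labs <- vapply(items, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("item labels must be unique", call. = FALSE)
  ns <- lengths(lapply(items, `[[`, "vector"))
  if (length(unique(ns)) != 1L) stop("dimension mismatch", call. = FALSE)
  structure(list(items = items, accept_threshold = accept_threshold),
            class = "cleanup_dictionary")
}

#' Clean up a noisy reconstruction
#'
#' Returns the dictionary item with maximal normalized correlation (cosine
#' similarity) to `v`. A score below the dictionary's `accept_threshold`
#' (or a zero query vector) yields an explicit no-match: label `NA` with
#' `matched = FALSE`. Exact ties break by dictionary order.
#'
#' @param v Numeric vector (e.g. from [unbind()]).
#' @param dict A [cleanup_dictionary()].
#' @return List with `label`, `score` and `matched`.
#' @export
cleanup <- function(v, dict) {
  stopifnot(inherits(dict, "cleanup_dictionary"))
  v <- item_vec(v)
  n <- length(dict$items[[1L]]$vector)
  if (length(v) != n) stop("dimension mismatch", call. = FALSE)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(list(label = NA_character_, score = 0, matched = FALSE))
  scores <- vapply(dict$items, function(it) sum(it$vector * v) / nv, numeric(1))
  i <- which.max(scores)
  if (scores[i] < dict$accept_threshold) {
    return(list(label = NA_character_, score = scores[i], matched = FALSE))
  }
  list(label = dict$items[[i]]$label, score = scores[i], matched = TRUE)
}

#' Build a pair memory (cue -> partner bindings)
#'
#' Convenience constructor: superposes `bind(cues[[i]], partners[[i]])`
#' over all pairs.
#'
#' @param cues,partners Equal-length lists of [holo_item()] objects.
#' @return A [holo_trace()].
#' @export
pair_memory <- function(cues, partners) {
  stopifnot(length(cues) == length(partners), length(cues) > 0L)
  superpose_traces(Map(bind, cues, partners))
}

#' Build a sequence memory
#'
#' Stores a sequence as the superposition of successive-element bindings
#' `advance(element_i) (*) element_{i+1}`, where `advance` is a fixed
#' component permutation of the cue vector. The permutation makes the
#' chain directional: binding is commutative, so binding raw successive
#' elements would let every recall step retrieve the predecessor exactly
#' as strongly as the successor and the walk would oscillate. The
#' permutation must not be a plain circular shift — shifts are phase
#' ramps in the Fourier domain and cancel out of every pairwise decode —
#' so a fixed affine index permutation (norm-preserving, decorrelating,
#' deterministic in the dimension) is used instead.
#'
#' @param items List of [holo_item()] objects in sequence order (>= 2).
#' @return A [holo_trace()].
#' @export
sequence_memory <- function(items) {
  stopifnot(length(items) >= 2L)
  pair_memory(lapply(items[-length(items)], advance_item), items[-1L])
}

# fixed directional marker: affine index permutation i -> a*i + 3 (mod n),
# with a the smallest candidate coprime to n; deterministic given n
advance_item <- function(it) {
  v <- item_vec(it)
  n <- length(v)
  a <- c(5L, 7L, 11L, 13L)
  a <- a[which(sapply(a, function(x) n %% x != 0L))[1L]]
  idx <- ((a * (seq_len(n) - 1L) + 3L) %% n) + 1L
  holo_item(v[idx], if (inherits(it, "holo_item")) it$label else "advanced")
}

#' Complete a stored sequence from a partial cue
#'
#' Iteratively unbinds the (advanced, see [sequence_memory()]) current
#' element from the memory, cleans the reconstruction up against the
#' dictionary, emits the recovered label and continues from it —
#' reconstructing the full temporal sequence from a fragment. Recall
#' stops after `k` steps or at the first no-match (a truncation warning
#' is raised if steps remained).
#'
#' @param memory A [holo_trace()] built by [sequence_memory()].
#' @param prefix Non-empty list of [holo_item()] objects already known;
#'   recall continues from the last one.
#' @param dict A [cleanup_dictionary()] over the sequence items.
#' @param k Maximum number of recall steps, >= 0.
#' @return Character vector of recovered labels (possibly empty).
#' @export
recall_sequence <- function(memory, prefix, dict, k) {
  stopifnot(inherits(memory, "holo_trace"), is.list(prefix),
            length(prefix) > 0L, inherits(dict, "cleanup_dictionary"))
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  labs <- vapply(dict$items, `[[`, character(1), "label")
  current <- prefix[[length(prefix)]]
  out <- character(0)
  for (step in seq_len(k)) {
    res <- cleanup(unbind(memory, advance_item(current)), dict)
    if (!res$matched) {
      if (step <= k) warning("sequence recall truncated at step ", step,
                             " (no match)")
      break
    }
    out <- c(out, res$label)
    current <- dict$items[[match(res$label, labs)]]
  }
  out
}

#' Degrade a trace (graceful degradation)
#'
#' Zeroes a uniformly random complement, keeping
#' `ceiling(keep_fraction * n)` components — the vector analogue of
#' cutting out a piece of a hologram. Recall from the fragment degrades
#' smoothly as the fragment shrinks. Uses the session RNG; seed it for
#' reproducibility.
#'
#' @param t A [holo_trace()].
#' @param keep_fraction Fraction of components kept, in `(0, 1]`.
#' @return A [holo_trace()] with the same `n_bindings`.
#' @export
degrade <- function(t, keep_fraction) {
  stopifnot(inherits(t, "holo_trace"))
  if (!is.finite(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]", call. = FALSE)
  }
  n <- length(t$vector)
  n_keep <- as.integer(ceiling(keep_fraction * n))
  if (n_keep >= n) return(t)
  keep <- sample.int(n, n_keep)
  v <- numeric(n)
  v[keep] <- t$vector[keep]
  holo_trace(v, n_bindings = t$n_bindings)
}

#' Map a spike train onto a holographic operand
#'
#' Bridges the temporal-code and holographic substrates: the train is
#' binned into `n` equal bins over `[0, span]`, each bin mapped to +1
#' (contains a spike) or -1 (empty), and the result normalized — a
#' bipolar temporal-pattern vector usable with [bind()] and [cleanup()].
#'
#' @param st A [spike_train()].
#' @param n Vector dimension (default 1024).
#' @param span Time span covered, seconds (default the train duration).
#' @param label Item label (default `"spikes"`).
#' @return A [holo_item()].
#' @export
spike_train_item <- function(st, n = 1024, span = NULL, label = "spikes") {
  stopifnot(inherits(st, "spike_train"))
  if (is.null(span)) span <- st$duration
  if (span <= 0) stop("span must be > 0", call. = FALSE)
  bins <- pmin(floor(st$times / span * n) + 1L, n)
  v <- rep(-1, n)
  v[unique(bins[st$times <= span])] <- 1
  holo_item(v, label)
}
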