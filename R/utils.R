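# Small shared helpers.

stop_arg <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
}

# Deterministic 31-bit seed derived from a base seed and any number of
# coordinates, so each benchmark cell/replicate is reproducible in isolation.
mix_seed <- function(base, ...) {
  parts <- c(base, unlist(list(...), use.names = FALSE))
  h <- 0
  for (p in parts) {
    v <- if (is.numeric(p)) as.numeric(p) else sum(utf8ToInt(as.character(p)))
    # fold a real-valued coordinate into an integer without collisions at the
    # resolution used in grids (1e6)
    v <- round(v * 1e6) %% 2147483647
    h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h)
}

# Align a (possibly named) vector with the tree's tip labels.
align_to_tips <- function(v, tip_labels, what = "vector") {
  if (!is.null(names(v))) {
    missing <- setdiff(tip_labels, names(v))
    if (length(missing))
      stop_arg(what, " is missing entries for tips: ",
               paste(head(missing, 5), collapse = ", "))
    v <- v[tip_labels]
  } else if (length(v) != length(tip_labels)) {
    stop_arg(what, " has length ", length(v), " but the tree has ",
             length(tip_labels), " tips")
  } else {
    names(v) <- tip_labels
  }
  v
}

trimws2 <- function(x) gsub("^\\s+|\\s+$", "", x)
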