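# Internal helpers: dotted-path access into the nested parameter list,
# scalar checks, money formatting.

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_fraction <- function(x) is_scalar_number(x) && x >= 0 && x <= 1

#' @noRd
split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

# Retrieve a leaf by dotted path; numeric components index unnamed lists
# (protocol lines), e.g. "protocols.M1.2.frequency.n".
path_get <- function(x, path) {
  for (key in split_path(path)) {
    idx <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
    if (is.list(x)) {
      if (is.character(idx) && !idx %in% names(x)) {
        stop("unknown parameter path component '", key, "' in '", path, "'",
          call. = FALSE
        )
      }
      if (is.numeric(idx) && idx > length(x)) {
        stop("index ", idx, " out of range in '", path, "'", call. = FALSE)
      }
      x <- x[[idx]]
    } else if (is.atomic(x) && !is.null(names(x)) && is.character(idx) &&
      idx %in% names(x)) {
      x <- unname(x[[idx]])
    } else {
      stop("unknown parameter path '", path, "'", call. = FALSE)
    }
  }
  x
}

path_set <- function(x, path, value) {
  keys <- split_path(path)
  if (length(keys) == 1L) {
    idx <- if (grepl("^[0-9]+$", keys)) as.integer(keys) else keys
    if (is.list(x) && is.character(idx) && !idx %in% names(x)) {
      stop("unknown parameter path component '", keys, "'", call. = FALSE)
    }
    if (is.atomic(x)) {
      if (!is.character(idx) || !idx %in% names(x)) {
        stop("unknown parameter path component '", keys, "'", call. = FALSE)
      }
      x[[idx]] <- value
    } else {
      x[[idx]] <- value
    }
    return(x)
  }
  head <- keys[1L]
  rest <- paste(keys[-1L], collapse = ".")
  idx <- if (grepl("^[0-9]+$", head)) as.integer(head) else head
  if (is.list(x) && is.character(idx) && !idx %in% names(x)) {
    stop("unknown parameter path component '", head, "'", call. = FALSE)
  }
  x[[idx]] <- path_set(x[[idx]], rest, value)
  x
}

fmt_sar <- function(x) formatC(x, format = "f", digits = 2, big.mark = ",")

`%||%` <- function(a, b) if (is.null(a)) b else a
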