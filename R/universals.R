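UNIVERSAL_TYPES <- c("narrow_word_order", "broad_word_order", "hierarchy", "other")

#' Specify an implicational universal "if X then Y"
#'
#' The condition may be a conjunction of feature=value literals (e.g.
#' "Adp-N and N-Num"); the result is a single literal. Types follow the
#' usual typological classification of proposed universals.
#'
#' @param id short unique identifier.
#' @param utype one of `"narrow_word_order"`, `"broad_word_order"`,
#'   `"hierarchy"`, `"other"`.
#' @param condition list of `list(feature =, value =)` literals (>= 1), or a
#'   named 0/1 vector.
#' @param result a single `list(feature =, value =)` literal or named scalar.
#' @param description free text.
#' @return a `universal_spec` object.
#' @export
universal_spec <- function(id, utype, condition, result, description = "") {
  utype <- match.arg(utype, UNIVERSAL_TYPES)
  condition <- as_literals(condition)
  result <- as_literals(result)
  if (length(condition) < 1) stop("condition needs at least one literal")
  if (length(result) != 1) stop("result must be a single literal")
  structure(
    list(id = as.character(id), utype = utype, condition = condition,
         result = result[[1]], description = description),
    class = "universal_spec"
  )
}

as_literals <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- lapply(seq_along(x), function(i) list(feature = names(x)[i],
                                               value = unname(x[i])))
  }
  if (!is.null(x$feature)) x <- list(x)
  lapply(x, function(l) {
    if (is.null(l$feature) || is.null(l$value)) {
      stop("each literal needs 'feature' and 'value'")
    }
    if (!l$value %in% c(0, 1)) stop("literal values must be 0 or 1")
    list(feature = as.character(l$feature), value = as.integer(l$value))
  })
}

#' @export
print.universal_spec <- function(x, ...) {
  cond <- paste(vapply(x$condition, function(l)
    sprintf("%s=%d", l$feature, l$value), ""), collapse = " AND ")
  cat(sprintf("universal %s [%s]: if %s then %s=%d\n", x$id, x$utype, cond,
              x$result$feature, x$result$value))
  invisible(x)
}

#' Read universal specifications from a YAML or JSON list
#'
#' Each entry must carry `id`, `utype`, `condition` (list of
#' `{feature, value}`), `result` (`{feature, value}`) and optionally
#' `description`.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return list of `universal_spec`.
#' @export
read_universals <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  lapply(raw, function(u) {
    universal_spec(u$id, u$utype, u$condition, u$result,
                   u$description %||% "")
  })
}

#' Compile a universal against a binary trait matrix
#'
#' Builds the paired binary variables per taxon: `x` is 1 iff all condition
#' literals hold, `y` is 1 iff the result literal holds. Taxa with a missing
#' value in any constituent feature are dropped (listwise deletion per
#' universal), so each universal is tested on the maximum number of taxa its
#' features allow.
#'
#' @param spec a `universal_spec`.
#' @param traits integer matrix (taxa x features, entries 0/1/NA) with taxon
#'   rownames.
#' @param min_n minimum sample size after deletion (default 100).
#' @return a `compiled_universal`: list with `taxa`, `x`, `y`, `n`,
#'   `universal_id`, `n_dropped`.
#' @export
compile_universal <- function(spec, traits, min_n = 100) {
  stopifnot(inherits(spec, "universal_spec"), is.matrix(traits))
  feats <- c(vapply(spec$condition, `[[`, "", "feature"),
             spec$result$feature)
  missing_feats <- setdiff(feats, colnames(traits))
  if (length(missing_feats)) {
    stop(sprintf("universal %s: features not in trait matrix: %s",
                 spec$id, paste(missing_feats, collapse = ", ")))
  }
  sub <- traits[, feats, drop = FALSE]
  keep <- rowSums(is.na(sub)) == 0
  sub <- sub[keep, , drop = FALSE]
  n <- nrow(sub)
  if (n < min_n) {
    stop(sprintf("universal %s: only %d taxa with complete data (minimum %d)",
                 spec$id, n, min_n))
  }
  x <- rep(1L, n)
  for (l in spec$condition) {
    x <- x & (sub[, l$feature] == l$value)
  }
  y <- as.integer(sub[, spec$result$feature] == spec$result$value)
  structure(
    list(taxa = rownames(sub), x = as.integer(x), y = y, n = n,
         universal_id = spec$id, n_dropped = sum(!keep)),
    class = "compiled_universal"
  )
}

#' @export
print.compiled_universal <- function(x, ...) {
  cat(sprintf("compiled universal %s: n = %d (%d dropped); P(x=1)=%.2f P(y=1)=%.2f\n",
              x$universal_id, x$n, x$n_dropped, mean(x$x), mean(x$y)))
  invisible(x)
}

FOUR_STATE_LETTERS <- c("A", "B", "C", "D")

#' Encode paired binary traits as a four-state variable
#'
#' States: 1/"A" = (0,0), 2/"B" = (0,1), 3/"C" = (1,0), 4/"D" = (1,1). State
#' 4 (both features present) is the harmonic state predicted by the
#' universal.
#'
#' @param x,y binary vectors of equal length, no missing values.
#' @return integer vector of states in 1..4 (names preserved from `x`).
#' @export
encode_four_state <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values: encode after compilation")
  if (!all(x %in% 0:1) || !all(y %in% 0:1)) stop("x and y must be 0/1")
  setNames(as.integer(1L + 2L * x + y), names(x))
}

#' Decode a four-state variable back to the trait pair
#' @param state integer vector in 1..4.
#' @return integer matrix with columns `x`, `y`.
#' @export
decode_four_state <- function(state) {
  if (!all(state %in% 1:4)) stop("states must be in 1..4")
  cbind(x = as.integer((state - 1L) %/% 2L), y = as.integer((state - 1L) %% 2L))
}

#' @rdname encode_four_state
#' @param state integer vector in 1..4.
#' @export
four_state_letter <- function(state) FOUR_STATE_LETTERS[state]
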