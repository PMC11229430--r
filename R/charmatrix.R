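# Cells are stored as integer bit masks over the digit states 0-9:
# bit s is set iff state s belongs to the cell's state set. A mask of 0 is
# MISSING ('?' or '-'); a mask with >1 bit is a polymorphic/ambiguous cell.
# This representation makes Fitch set operations plain integer bit ops.

MAX_STATES <- 10L

state_mask <- function(states) {
  m <- 0L
  for (s in states) m <- bitwOr(m, bitwShiftL(1L, s))
  m
}

mask_states <- function(mask) which(bitwAnd(bitwShiftR(mask, 0:9), 1L) == 1L) - 1L

popcount10 <- function(x) {
  n <- integer(length(x))
  for (s in 0:9) n <- n + bitwAnd(bitwShiftR(x, s), 1L)
  n
}

#' Construct a morphological character matrix
#'
#' Builds a `char_matrix` from one token string per taxon, using the usual
#' NEXUS/TNT cell symbols: single digits `0`-`9` for states, `?` and `-` for
#' missing/inapplicable (both stored as MISSING), and `[01]`, `(01)` or
#' `{01}` for polymorphic or ambiguous cells, which are stored as the state
#' set and scored as ambiguity.
#'
#' @param rows named character vector; names are taxon labels, values are the
#'   token strings, one cell after another (whitespace ignored).
#' @param partitions `NULL` (a single partition `"all"`), a character vector
#'   with one label per character, or a specification string such as
#'   `"adult=1-61,larval=62-93"` with 1-based inclusive ranges covering every
#'   character exactly once.
#' @return An object of class `char_matrix` with fields `taxa`, `bits`
#'   (taxa x characters integer mask matrix), `poly` (logical matrix, `TRUE`
#'   where the source token was a bracketed group), `partitions` and
#'   `symbols` (the declared or observed state universe).
#' @examples
#' cm <- char_matrix(c(A = "01?", B = "1[01]-"))
#' count_coded(cm, "A")
#' @export
char_matrix <- function(rows, partitions = NULL) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("char_matrix(): 'rows' must be a named character vector")
  }
  parsed <- lapply(rows, tokenize_cells)
  nch <- lengths(lapply(parsed, `[[`, "mask"))
  if (length(unique(nch)) != 1L) {
    bad <- names(rows)[which(nch != nch[1L])[1L]]
    stop(sprintf("ragged matrix: taxon '%s' has %d cells, expected %d",
                 bad, nch[names(rows) == bad][1L], nch[1L]))
  }
  bits <- do.call(rbind, lapply(parsed, `[[`, "mask"))
  poly <- do.call(rbind, lapply(parsed, `[[`, "poly"))
  rownames(bits) <- rownames(poly) <- names(rows)
  new_char_matrix(bits, poly, partitions = partitions)
}

new_char_matrix <- function(bits, poly, partitions = NULL, symbols = NULL) {
  taxa <- rownames(bits)
  if (anyDuplicated(taxa)) {
    stop(sprintf("duplicate taxon label: '%s'", taxa[duplicated(taxa)][1L]))
  }
  nc <- ncol(bits)
  if (nc == 0L) stop("matrix has zero characters")
  part <- resolve_partitions(partitions, nc)
  if (is.null(symbols)) {
    symbols <- sort(mask_states(Reduce(bitwOr, as.integer(bits), 0L)))
    if (length(symbols) == 0L) symbols <- 0L
  }
  cm <- structure(list(taxa = taxa, bits = bits, poly = poly,
                       partitions = part, symbols = as.integer(symbols)),
                  class = "char_matrix")
  validate_char_matrix(cm)
  cm
}

validate_char_matrix <- function(cm) {
  universe <- state_mask(cm$symbols)
  extra <- matrix(bitwAnd(as.integer(cm$bits), bitwNot(universe)),
                  nrow(cm$bits))
  if (any(extra != 0L)) {
    j <- which(colSums(extra != 0L) > 0L)[1L]
    stop(sprintf("character %d uses a state symbol outside the declared set {%s}",
                 j, paste(cm$symbols, collapse = ",")))
  }
  if (length(cm$partitions) != ncol(cm$bits)) {
    stop("partition labels do not cover all characters exactly once")
  }
  invisible(cm)
}

resolve_partitions <- function(partitions, nc) {
  if (is.null(partitions)) return(rep("all", nc))
  if (length(partitions) == 1L && grepl("=", partitions, fixed = TRUE)) {
    return(parse_partition_spec(partitions, nc))
  }
  if (length(partitions) != nc) {
    stop(sprintf("partition vector has length %d, matrix has %d characters",
                 length(partitions), nc))
  }
  as.character(partitions)
}

# "adult=1-61,larval=62-93" -> per-character label vector (1-based inclusive
# ranges in the spec string, converted internally).
parse_partition_spec <- function(spec, nc) {
  out <- rep(NA_character_, nc)
  for (piece in strsplit(spec, ",", fixed = TRUE)[[1L]]) {
    kv <- strsplit(trimws(piece), "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop(sprintf("bad partition piece '%s'", piece))
    idx <- parse_index_list(kv[2L])
    if (any(idx < 1L | idx > nc)) {
      stop(sprintf("partition '%s' indexes outside 1..%d", kv[1L], nc))
    }
    if (any(!is.na(out[idx]))) {
      stop(sprintf("partition '%s' overlaps another partition", kv[1L]))
    }
    out[idx] <- trimws(kv[1L])
  }
  if (anyNA(out)) {
    stop(sprintf("partitions do not cover characters: %s uncovered",
                 paste(utils::head(which(is.na(out)), 5L), collapse = ",")))
  }
  out
}

parse_index_list <- function(txt) {
  pieces <- strsplit(trimws(txt), "[[:space:]+]+")[[1L]]
  idx <- integer(0)
  for (p in pieces[nzchar(pieces)]) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      if (length(ab) != 2L || anyNA(ab)) stop(sprintf("bad index range '%s'", p))
      idx <- c(idx, seq.int(ab[1L], ab[2L]))
    } else {
      v <- suppressWarnings(as.integer(p))
      if (is.na(v)) stop(sprintf("bad index '%s'", p))
      idx <- c(idx, v)
    }
  }
  idx
}

# One row of cell tokens -> masks + polymorphic flags.
tokenize_cells <- function(txt) {
  chars <- strsplit(gsub("[[:space:]]", "", txt), "")[[1L]]
  mask <- integer(0); poly <- logical(0)
  i <- 1L
  closers <- c("[" = "]", "(" = ")", "{" = "}")
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("?", "-")) {
      mask <- c(mask, 0L); poly <- c(poly, FALSE)
    } else if (grepl("^[0-9]$", ch)) {
      mask <- c(mask, bitwShiftL(1L, as.integer(ch))); poly <- c(poly, FALSE)
    } else if (ch %in% names(closers)) {
      j <- i + 1L; grp <- integer(0)
      while (j <= length(chars) && chars[j] != closers[ch]) {
        if (!grepl("^[0-9]$", chars[j])) {
          stop(sprintf("bad symbol '%s' inside state group", chars[j]))
        }
        grp <- c(grp, as.integer(chars[j])); j <- j + 1L
      }
      if (j > length(chars)) stop("unterminated state group")
      if (length(grp) == 0L) stop("empty state group")
      mask <- c(mask, state_mask(grp)); poly <- c(poly, TRUE)
      i <- j
    } else {
      stop(sprintf("unexpected cell symbol '%s'", ch))
    }
    i <- i + 1L
  }
  list(mask = mask, poly = poly)
}

#' @export
dim.char_matrix <- function(x) c(length(x$taxa), ncol(x$bits))

#' Number of characters in a matrix
#' @param cm a `char_matrix`.
#' @export
n_characters <- function(cm) ncol(cm$bits)

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters\n",
              length(x$taxa), ncol(x$bits)))
  tab <- table(x$partitions)
  cat("partitions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("states:", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

taxon_row <- function(cm, taxon) {
  i <- match(taxon, cm$taxa)
  if (is.na(i)) stop(sprintf("unknown taxon '%s'", taxon))
  i
}

#' Count coded cells for a taxon
#'
#' A cell is coded when it carries at least one observed state; `?` and `-`
#' cells are not coded. Restricting to a partition reproduces census numbers
#' such as "31 adult characters coded for the fossil".
#'
#' @param cm a `char_matrix`.
#' @param taxon taxon label.
#' @param partition partition label, or `"ALL"` for the whole matrix.
#' @return integer count.
#' @export
count_coded <- function(cm, taxon, partition = "ALL") {
  i <- taxon_row(cm, taxon)
  keep <- if (identical(partition, "ALL")) rep(TRUE, ncol(cm$bits))
          else cm$partitions == partition
  if (!identical(partition, "ALL") && !any(keep)) {
    stop(sprintf("unknown partition '%s'", partition))
  }
  sum(cm$bits[i, keep] != 0L)
}

# Vectorised minimum steps m_i for a set of characters, optionally restricted
# to a taxon subset (placement scores use the taxa actually on the tree).
# d = number of distinct states among monomorphic coded cells; m = max(0, d-1).
# Polymorphic cells never raise d: they can adopt an already-counted state.
min_steps_vec <- function(cm, chars = NULL, taxa = NULL) {
  if (is.null(chars)) chars <- seq_len(ncol(cm$bits))
  rows <- if (is.null(taxa)) seq_along(cm$taxa) else
    vapply(taxa, taxon_row, integer(1L), cm = cm)
  b <- cm$bits[rows, chars, drop = FALSE]
  mono <- b != 0L & bitwAnd(b, b - 1L) == 0L
  mb <- b; mb[!mono] <- 0L
  uni <- rep(0L, length(chars))
  for (i in seq_along(rows)) uni <- bitwOr(uni, mb[i, ])
  pmax(0L, popcount10(uni) - 1L)
}

#' Minimum conceivable steps for one character
#'
#' The lower bound `m = max(0, d - 1)` where `d` is the number of distinct
#' states observed in monomorphic coded cells. This is the baseline used by
#' implied weighting's extra-steps computation.
#'
#' @inheritParams count_coded
#' @param char 1-based character index.
#' @param taxa optional subset of taxa over which to count.
#' @export
min_steps <- function(cm, char, taxa = NULL) {
  if (char < 1L || char > ncol(cm$bits)) stop("character index out of range")
  as.integer(min_steps_vec(cm, chars = char, taxa = taxa))
}

#' Is a character parsimony-informative?
#'
#' `TRUE` iff at least two states each occur in at least two monomorphic
#' coded cells, i.e. the character can differ in length between trees.
#'
#' @inheritParams min_steps
#' @export
is_parsimony_informative <- function(cm, char) {
  if (char < 1L || char > ncol(cm$bits)) stop("character index out of range")
  b <- cm$bits[, char]
  mono <- b[b != 0L & bitwAnd(b, b - 1L) == 0L]
  if (length(mono) == 0L) return(FALSE)
  sum(table(mono) >= 2L) >= 2L
}

## ---- file I/O ---------------------------------------------------------

#' Parse a character matrix from NEXUS or TNT text
#'
#' Understands a non-interleaved NEXUS `MATRIX` block (with optional
#' `DIMENSIONS`, `FORMAT SYMBOLS` and `CHARSET` commands) and the TNT
#' `xread` block. `?` and `-` both map to MISSING; bracketed groups map to
#' multi-state cells flagged polymorphic.
#'
#' @param text raw file content as a single string or character vector of
#'   lines.
#' @param dialect `"auto"` (detect from content), `"nexus"` or `"tnt"`.
#' @param partitions optional partition specification (see [char_matrix()]);
#'   overrides any `CHARSET` commands found in the file.
#' @return a `char_matrix`.
#' @export
parse_char_matrix <- function(text, dialect = c("auto", "nexus", "tnt"),
                              partitions = NULL) {
  dialect <- match.arg(dialect)
  text <- paste(text, collapse = "\n")
  if (dialect == "auto") {
    dialect <- if (grepl("#NEXUS", text, ignore.case = TRUE)) "nexus"
               else if (grepl("\\bxread\\b", text, ignore.case = TRUE)) "tnt"
               else stop("cannot detect matrix dialect (no #NEXUS, no xread)")
  }
  if (dialect == "nexus") parse_nexus_matrix(text, partitions)
  else parse_tnt_matrix(text, partitions)
}

#' Read a character matrix from a file
#' @param file path to a NEXUS or TNT file.
#' @inheritParams parse_char_matrix
#' @export
read_char_matrix <- function(file, dialect = c("auto", "nexus", "tnt"),
                             partitions = NULL) {
  parse_char_matrix(readLines(file, warn = FALSE), dialect = dialect,
                    partitions = partitions)
}

# Strip NEXUS [comments], but keep bracket groups consisting purely of state
# digits (TNT-style polymorphism, which the MATRIX tokenizer consumes).
strip_nexus_comments <- function(text) {
  gsub("\\[[^][]*[^][0-9 \t][^][]*\\]", " ", text)
}

parse_nexus_matrix <- function(text, partitions = NULL) {
  text <- strip_nexus_comments(text)
  m <- regexpr("(?i)\\bmatrix\\b", text, perl = TRUE)
  if (m == -1L) stop("no MATRIX block found")
  rest <- substring(text, m + attr(m, "match.length"))
  end <- regexpr(";", rest, fixed = TRUE)
  if (end == -1L) stop("MATRIX block not terminated by ';'")
  block <- substring(rest, 1L, end - 1L)

  sym <- NULL
  fm <- regmatches(text, regexpr("(?i)symbols\\s*=\\s*\"[^\"]*\"", text, perl = TRUE))
  if (length(fm) == 1L) {
    digs <- regmatches(fm, gregexpr("[0-9]", fm))[[1L]]
    if (length(digs)) sym <- sort(as.integer(digs))
  }

  rows <- parse_matrix_rows(block)
  dims <- parse_nexus_dimensions(text)
  cm <- build_matrix_from_rows(rows, dims, partitions %||%
                                 parse_nexus_charsets(text), sym)
  cm
}

parse_nexus_dimensions <- function(text) {
  out <- list(ntax = NA_integer_, nchar = NA_integer_)
  g <- regmatches(text, regexpr("(?i)ntax\\s*=\\s*[0-9]+", text, perl = TRUE))
  if (length(g)) out$ntax <- as.integer(sub("(?i)ntax\\s*=\\s*", "", g, perl = TRUE))
  g <- regmatches(text, regexpr("(?i)nchar\\s*=\\s*[0-9]+", text, perl = TRUE))
  if (length(g)) out$nchar <- as.integer(sub("(?i)nchar\\s*=\\s*", "", g, perl = TRUE))
  out
}

# CHARSET adult = 1-61;  -> partition label vector builder (returns the spec
# string form understood by resolve_partitions, or NULL when absent).
parse_nexus_charsets <- function(text) {
  hits <- regmatches(text,
    gregexpr("(?i)charset\\s+[A-Za-z_][A-Za-z0-9_.]*\\s*=\\s*[-0-9 \t]+;",
             text, perl = TRUE))[[1L]]
  if (length(hits) == 0L) return(NULL)
  pieces <- vapply(hits, function(h) {
    h <- sub("(?i)^charset\\s+", "", h, perl = TRUE)
    h <- sub(";$", "", h)
    kv <- strsplit(h, "=")[[1L]]
    sprintf("%s=%s", trimws(kv[1L]), trimws(kv[2L]))
  }, character(1L), USE.NAMES = FALSE)
  paste(pieces, collapse = ",")
}

parse_matrix_rows <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty MATRIX block")
  labels <- character(0); data <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "'")) {
      close <- regexpr("'", substring(ln, 2L), fixed = TRUE)
      if (close == -1L) stop("unterminated quoted taxon label")
      lab <- substring(ln, 2L, close)
      rest <- substring(ln, close + 2L)
    } else {
      sp <- regexpr("[ \t]", ln)
      if (sp == -1L) stop(sprintf("matrix row '%s' has no character data", ln))
      lab <- substring(ln, 1L, sp - 1L)
      rest <- substring(ln, sp + 1L)
    }
    if (lab %in% labels) stop(sprintf("duplicate taxon label: '%s'", lab))
    labels <- c(labels, lab)
    data <- c(data, gsub("[ \t]", "", rest))
  }
  stats::setNames(data, labels)
}

build_matrix_from_rows <- function(rows, dims, partitions, symbols) {
  cm <- char_matrix(rows, partitions = partitions)
  if (!is.null(symbols)) {
    cm <- new_char_matrix(cm$bits, cm$poly, cm$partitions, symbols)
  }
  if (!is.na(dims$ntax) && dims$ntax != length(cm$taxa)) {
    stop(sprintf("DIMENSIONS declares %d taxa, matrix has %d",
                 dims$ntax, length(cm$taxa)))
  }
  if (!is.na(dims$nchar) && dims$nchar != ncol(cm$bits)) {
    stop(sprintf("DIMENSIONS declares %d characters, matrix has %d",
                 dims$nchar, ncol(cm$bits)))
  }
  cm
}

parse_tnt_matrix <- function(text, partitions = NULL) {
  m <- regexpr("(?i)\\bxread\\b", text, perl = TRUE)
  if (m == -1L) stop("no xread block found")
  rest <- substring(text, m + attr(m, "match.length"))
  # optional 'title'
  rest <- sub("^\\s*'[^']*'", "", rest)
  head <- regmatches(rest, regexpr("^\\s*([0-9]+)\\s+([0-9]+)", rest))
  if (length(head) == 0L) stop("xread: missing nchar/ntax header")
  nums <- as.integer(strsplit(trimws(head), "\\s+")[[1L]])
  rest <- substring(rest, nchar(head) + 1L)
  end <- regexpr(";", rest, fixed = TRUE)
  if (end == -1L) stop("xread block not terminated by ';'")
  rows <- parse_matrix_rows(substring(rest, 1L, end - 1L))
  build_matrix_from_rows(rows, list(ntax = nums[2L], nchar = nums[1L]),
                         partitions, NULL)
}

cell_token <- function(mask, poly) {
  if (mask == 0L) return("?")
  st <- mask_states(mask)
  if (length(st) == 1L && !poly) return(as.character(st))
  sprintf("[%s]", paste(st, collapse = ""))
}

#' Write a character matrix as NEXUS
#'
#' Emits a `DATA` block (standard datatype, `?` missing, `-` gap) and, when
#' the matrix has more than one partition, a `SETS` block with one `CHARSET`
#' per partition so the partition structure round-trips.
#'
#' @param cm a `char_matrix`.
#' @param file path, or `NULL` to return the text invisibly.
#' @export
write_nexus_matrix <- function(cm, file = NULL) {
  nt <- length(cm$taxa); nc <- ncol(cm$bits)
  wid <- max(nchar(cm$taxa)) + 2L
  rows <- vapply(seq_len(nt), function(i) {
    toks <- vapply(seq_len(nc), function(j)
      cell_token(cm$bits[i, j], cm$poly[i, j]), character(1L))
    sprintf("  %-*s%s", wid, cm$taxa[i], paste(toks, collapse = ""))
  }, character(1L))
  out <- c("#NEXUS", "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nt, nc),
           sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
                   paste(cm$symbols, collapse = " ")),
           "  MATRIX", rows, "  ;", "END;")
  parts <- unique(cm$partitions)
  if (length(parts) > 1L) {
    cs <- vapply(parts, function(p) {
      idx <- which(cm$partitions == p)
      sprintf("  CHARSET %s = %s;", p, format_index_runs(idx))
    }, character(1L))
    out <- c(out, "BEGIN SETS;", cs, "END;")
  }
  txt <- paste(out, collapse = "\n")
  if (is.null(file)) return(invisible(txt))
  writeLines(txt, file)
  invisible(txt)
}

format_index_runs <- function(idx) {
  idx <- sort(idx)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r) else sprintf("%d-%d", r[1L], r[length(r)])
  }, character(1L)), collapse = " ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
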