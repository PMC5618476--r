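#' Resolve an atom selection
#'
#' A small selection grammar in the spirit of trajectory-analysis tools:
#' \describe{
#'   \item{`resid A-B` / `resid A,B,C`}{author-numbered residue ranges/lists
#'     (ranges and lists may be mixed, e.g. `resid 698-844,877`).}
#'   \item{`name CA` / `name OD1,OG1`}{atom names.}
#'   \item{`backbone`}{shorthand for atom names N, CA, C, O.}
#'   \item{`resname HF`}{residue names.}
#'   \item{`term and term`}{set intersection.}
#'   \item{`within R of <subquery>`}{all residues, other than those of the
#'     subquery itself, whose nearest heavy atom lies strictly closer than
#'     `R` Angstrom to any heavy atom of the subquery; whole residues are
#'     selected. Requires `frame` (distances are frame-dependent). Must be
#'     the last term of a conjunction.}
#' }
#' Resolution is deterministic: the same query on the same topology (and
#' frame) always yields the same sorted, unique 1-based atom index set. An
#' empty result is an error, never a silently empty selection.
#'
#' @param top a [topology()].
#' @param query selection string.
#' @param frame optional n_atoms x 3 coordinate matrix, required by `within`.
#' @return object of class `"selection"`: list with `query` and sorted
#'   integer `indices`.
#' @examples
#' top <- generate_topology()
#' sel <- select(top, "resid 873-908 and name CA")
#' length(sel$indices)  # 36 lid C-alpha atoms
#' @export
select <- function(top, query, frame = NULL) {
  stopifnot(inherits(top, "topology"))
  if (!is.character(query) || length(query) != 1L || !nzchar(trimws(query))) {
    stop("selection query must be a non-empty string")
  }
  idx <- .resolve_query(top, trimws(query), frame, offset = 0L)
  if (length(idx) == 0L) {
    stop("selection '", query, "' matches no atoms")
  }
  structure(list(query = query, indices = sort(unique(idx))),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("selection '", x$query, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

# Resolve a (sub)query to (possibly empty) indices. `offset` is the character
# position of the subquery within the original string, for error messages.
.resolve_query <- function(top, query, frame, offset) {
  # `within R of <rest>` consumes the remainder of the string, so split the
  # conjunction only over the part before any `within`.
  m <- regexpr("(^|\\s)within\\s", query)
  if (m > 0L) {
    head_part <- substr(query, 1L, m - 1L)
    within_part <- trimws(substr(query, m, nchar(query)))
    idx_w <- .resolve_within(top, within_part, frame, offset + m - 1L)
    if (!nzchar(trimws(head_part))) return(idx_w)
    head_part <- sub("\\s+and\\s*$", "", head_part)
    idx_h <- .resolve_conjunction(top, head_part, frame, offset)
    return(intersect(idx_h, idx_w))
  }
  .resolve_conjunction(top, query, frame, offset)
}

.resolve_conjunction <- function(top, query, frame, offset) {
  terms <- strsplit(query, "\\s+and\\s+")[[1L]]
  if (length(terms) == 0L) stop("empty selection term at position ", offset + 1L)
  idx <- seq_len(top$n_atoms)
  pos <- offset
  for (tm in terms) {
    idx <- intersect(idx, .resolve_term(top, trimws(tm), pos))
    pos <- pos + nchar(tm) + 5L  # approximate position of next term
  }
  idx
}

.resolve_term <- function(top, term, pos) {
  a <- top$atoms
  toks <- strsplit(term, "\\s+")[[1L]]
  kw <- toks[1L]
  if (kw == "backbone") {
    if (length(toks) != 1L) stop("grammar error after 'backbone' at position ", pos + 1L)
    return(which(a$atom_name %in% c("N", "CA", "C", "O") & a$record == "ATOM"))
  }
  if (length(toks) != 2L) {
    stop("grammar error in term '", term, "' at position ", pos + 1L,
         " (expected '", kw, " <value>')")
  }
  arg <- toks[2L]
  switch(kw,
    resid = which(a$residue_id %in% .parse_resid_spec(arg, pos)),
    name = which(a$atom_name %in% strsplit(arg, ",")[[1L]]),
    resname = which(a$residue_name %in% strsplit(arg, ",")[[1L]]),
    stop("unknown selection keyword '", kw, "' at position ", pos + 1L)
  )
}

.parse_resid_spec <- function(spec, pos) {
  parts <- strsplit(spec, ",")[[1L]]
  ids <- integer(0)
  for (p in parts) {
    if (grepl("^-?[0-9]+--?[0-9]+$", p) && grepl("-", substr(p, 2L, nchar(p)))) {
      # split "A-B" at the first interior dash
      dash <- regexpr("-", substr(p, 2L, nchar(p))) + 1L
      lo <- as.integer(substr(p, 1L, dash - 1L))
      hi <- as.integer(substr(p, dash + 1L, nchar(p)))
      if (is.na(lo) || is.na(hi) || hi < lo) {
        stop("bad residue range '", p, "' at position ", pos + 1L)
      }
      ids <- c(ids, lo:hi)
    } else {
      v <- suppressWarnings(as.integer(p))
      if (is.na(v)) stop("bad residue id '", p, "' at position ", pos + 1L)
      ids <- c(ids, v)
    }
  }
  ids
}

.resolve_within <- function(top, term, frame, pos) {
  m <- regmatches(term, regexec("^within\\s+([0-9.]+)\\s+of\\s+(.+)$", term))[[1L]]
  if (length(m) != 3L) {
    stop("grammar error in '", term, "' at position ", pos + 1L,
         " (expected 'within R of <subquery>')")
  }
  r <- as.numeric(m[2L])
  if (is.null(frame)) stop("'within' selections require a reference frame")
  stopifnot(is.matrix(frame), nrow(frame) == top$n_atoms)
  sub_idx <- .resolve_query(top, m[3L], frame, pos)
  if (length(sub_idx) == 0L) stop("'within' subquery '", m[3L], "' matches no atoms")
  a <- top$atoms
  heavy <- a$element != "H"
  ref <- intersect(sub_idx, which(heavy))
  if (length(ref) == 0L) stop("'within' subquery has no heavy atoms")
  sub_res <- unique(a$residue_id[sub_idx])
  cand_res <- setdiff(unique(a$residue_id), sub_res)
  hit <- logical(0)
  out <- integer(0)
  refxyz <- frame[ref, , drop = FALSE]
  for (res in cand_res) {
    atoms_r <- which(a$residue_id == res & heavy)
    if (length(atoms_r) == 0L) next
    d2min <- min(.cross_dist2(frame[atoms_r, , drop = FALSE], refxyz))
    if (sqrt(d2min) < r) {  # strict < R
      out <- c(out, which(a$residue_id == res))
    }
  }
  out
}

# squared distances between two coordinate sets (na x nb)
.cross_dist2 <- function(xa, xb) {
  outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
}
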