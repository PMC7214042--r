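# Alignment container and Stockholm / FASTA / WUSS input-output.
#
# Internal residue codes: A=1, C=2, G=3, U=4, gap=0, ambiguity/missing=5.
# T is normalized to U on input; case is preserved in storage but ignored
# for all statistics. Gap characters -, ., _, ~ are equivalent.

GAP_CHARS <- c("-", ".", "_", "~")
WUSS_UNPAIRED <- c(".", ",", "_", "-", ":", "~")

#' Construct an alignment object
#'
#' @param names character vector of unique, non-empty sequence identifiers.
#' @param rows character vector of equal-length gapped sequences.
#' @param ss_cons optional WUSS consensus-structure string of the same length
#'   as the alignment.
#' @param metadata free-form named list of annotations.
#' @return an object of class `covaln` with fields `names`, `rows`, `L`,
#'   `ss_cons`, `metadata`.
#' @export
new_alignment <- function(names, rows, ss_cons = NULL, metadata = list()) {
  if (length(names) == 0L) cp_format_error("alignment has no sequences")
  if (length(names) != length(rows)) {
    cp_format_error("names and rows differ in length")
  }
  names <- as.character(names)
  rows <- as.character(rows)
  if (anyDuplicated(names)) {
    cp_format_error("duplicate sequence names: ",
                    paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (any(!nzchar(names))) cp_format_error("empty sequence name")
  L <- unique(nchar(rows))
  if (length(L) != 1L) {
    cp_format_error("ragged alignment: row lengths ", paste(sort(L), collapse = ", "))
  }
  if (L < 1L) cp_format_error("alignment has zero columns")
  if (!is.null(ss_cons)) {
    ss_cons <- as.character(ss_cons)
    if (nchar(ss_cons) != L) {
      cp_format_error("SS_cons length ", nchar(ss_cons),
                      " does not match alignment length ", L)
    }
  }
  structure(list(names = names, rows = rows, L = as.integer(L),
                 ss_cons = ss_cons, metadata = metadata),
            class = "covaln")
}

#' @export
print.covaln <- function(x, ...) {
  cat(sprintf("RNA alignment: %d sequences x %d columns%s\n",
              length(x$names), x$L,
              if (is.null(x$ss_cons)) "" else " (with SS_cons)"))
  invisible(x)
}

#' Encode an alignment as an integer matrix
#'
#' @param aln a `covaln` object.
#' @return integer matrix (sequences x columns), rownames = sequence names;
#'   codes A=1, C=2, G=3, U=4, gap=0, ambiguity=5.
#' @export
aln_matrix <- function(aln) {
  chars <- matrix(unlist(strsplit(toupper(aln$rows), "", fixed = TRUE)),
                  nrow = length(aln$rows), byrow = TRUE)
  m <- matrix(5L, nrow = nrow(chars), ncol = ncol(chars))
  m[chars %in% GAP_CHARS] <- 0L
  m[chars == "A"] <- 1L
  m[chars == "C"] <- 2L
  m[chars == "G"] <- 3L
  m[chars %in% c("U", "T")] <- 4L
  rownames(m) <- aln$names
  m
}

decode_matrix <- function(m) {
  lut <- c("-", "A", "C", "G", "U", "N")
  apply(m, 1L, function(r) paste(lut[r + 1L], collapse = ""))
}

#' Read a Stockholm 1.0 alignment
#'
#' Supports interleaved (multi-block) files; sequence blocks and per-block
#' `#=GC SS_cons` segments are concatenated. T is normalized to U.
#'
#' @param path path to a Stockholm file.
#' @return a [new_alignment()] object; `#=GF` annotations land in `metadata`.
#' @export
read_stockholm <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first) || !grepl("^# STOCKHOLM 1\\.0", first)) {
    cp_format_error("not a Stockholm file (missing '# STOCKHOLM 1.0' header): ", path)
  }
  seqs <- list()
  ord <- character()
  ss_segments <- character()
  metadata <- list()
  block_seen <- character()
  started <- FALSE
  for (ln in lines) {
    if (!started) { started <- grepl("^# STOCKHOLM 1\\.0", ln); next }
    if (grepl("^//", ln)) break
    if (!nzchar(trimws(ln))) { block_seen <- character(); next }
    if (grepl("^#=GC\\s+SS_cons\\s+\\S", ln)) {
      ss_segments <- c(ss_segments, sub("^#=GC\\s+SS_cons\\s+(\\S+)\\s*$", "\\1", ln))
      next
    }
    if (grepl("^#=GF\\s+\\S+\\s+\\S", ln)) {
      tag <- sub("^#=GF\\s+(\\S+)\\s.*$", "\\1", ln)
      val <- sub("^#=GF\\s+\\S+\\s+(.*)$", "\\1", ln)
      metadata[[tag]] <- if (is.null(metadata[[tag]])) val else paste(metadata[[tag]], val)
      next
    }
    if (grepl("^#", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) {
      cp_format_error("malformed sequence line in ", path, ": ", ln)
    }
    nm <- parts[1]
    if (nm %in% block_seen) {
      cp_format_error("duplicate sequence name within block: ", nm)
    }
    block_seen <- c(block_seen, nm)
    if (is.null(seqs[[nm]])) {
      seqs[[nm]] <- parts[2]
      ord <- c(ord, nm)
    } else {
      seqs[[nm]] <- paste0(seqs[[nm]], parts[2])
    }
  }
  if (length(ord) == 0L) cp_format_error("no sequences in ", path)
  rows <- chartr("Tt", "Uu", unlist(seqs[ord], use.names = FALSE))
  ss <- if (length(ss_segments)) paste(ss_segments, collapse = "") else NULL
  new_alignment(ord, rows, ss_cons = ss, metadata = metadata)
}

#' Write a Stockholm 1.0 alignment (single block)
#'
#' @param aln a `covaln` object.
#' @param path output file path.
#' @return invisibly, `path`. [read_stockholm()] inverts this.
#' @export
write_stockholm <- function(aln, path) {
  stopifnot(inherits(aln, "covaln"))
  w <- max(nchar(aln$names), nchar("#=GC SS_cons"))
  lines <- c("# STOCKHOLM 1.0", "")
  for (tag in names(aln$metadata)) {
    lines <- c(lines, sprintf("#=GF %s %s", tag, aln$metadata[[tag]]))
  }
  lines <- c(lines, sprintf("%-*s %s", w, aln$names, aln$rows))
  if (!is.null(aln$ss_cons)) {
    lines <- c(lines, sprintf("%-*s %s", w, "#=GC SS_cons", aln$ss_cons))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read an aligned (gapped) FASTA file as an alignment
#'
#' Secondary input format; FASTA carries no consensus structure, so a
#' structure must be supplied separately when one is needed.
#'
#' @param path path to an aligned FASTA file.
#' @return a [new_alignment()] object.
#' @export
read_fasta_msa <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) cp_format_error("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  nms <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  rows <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  new_alignment(nms, chartr("Tt", "Uu", unname(rows)))
}

#' Construct a secondary structure from basepair indices
#'
#' @param i,j integer vectors of 1-based column indices with `i < j`
#'   elementwise; every column may occur in at most one pair.
#' @return an object of class `rna_structure` with fields `pairs` (two-column
#'   integer matrix) and `B` (number of pairs).
#' @export
secondary_structure <- function(i = integer(), j = integer()) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j)) cp_structure_error("i and j differ in length")
  if (any(i >= j)) cp_structure_error("basepairs must satisfy i < j")
  if (any(i < 1L)) cp_structure_error("column indices are 1-based")
  cols <- c(i, j)
  if (anyDuplicated(cols)) {
    cp_structure_error("column ", cols[duplicated(cols)][1], " occurs in two basepairs")
  }
  o <- order(i)
  pairs <- cbind(i = i[o], j = j[o])
  structure(list(pairs = pairs, B = nrow(pairs)), class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA secondary structure: %d basepairs\n", x$B))
  invisible(x)
}

#' Parse a WUSS consensus-structure string into basepairs
#'
#' Matched brackets `<> () [] {}` are nested pair families; uppercase letters
#' open and the corresponding lowercase letters close pseudoknot families;
#' `. , _ - : ~` are unpaired.
#'
#' @param ss a WUSS string.
#' @return a [secondary_structure()] with 1-based column indices.
#' @export
pairs_from_wuss <- function(ss) {
  if (!is.character(ss) || length(ss) != 1L || !nzchar(ss)) {
    cp_structure_error("empty structure string")
  }
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  close_of <- c(">" = "<", ")" = "(", "]" = "[", "}" = "{")
  stacks <- list()
  pi <- integer(); pj <- integer()
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch %in% c("<", "(", "[", "{")) {
      stacks[[ch]] <- c(stacks[[ch]], k)
    } else if (ch %in% names(close_of)) {
      key <- close_of[[ch]]
      if (length(stacks[[key]]) == 0L) {
        cp_structure_error("unbalanced '", ch, "' at column ", k)
      }
      n <- length(stacks[[key]])
      pi <- c(pi, stacks[[key]][n]); pj <- c(pj, k)
      stacks[[key]] <- stacks[[key]][-n]
    } else if (grepl("^[A-Z]$", ch)) {
      stacks[[ch]] <- c(stacks[[ch]], k)
    } else if (grepl("^[a-z]$", ch)) {
      key <- toupper(ch)
      if (length(stacks[[key]]) == 0L) {
        cp_structure_error("unmatched pseudoknot close '", ch, "' at column ", k)
      }
      n <- length(stacks[[key]])
      pi <- c(pi, stacks[[key]][n]); pj <- c(pj, k)
      stacks[[key]] <- stacks[[key]][-n]
    } else if (!(ch %in% WUSS_UNPAIRED)) {
      cp_structure_error("unknown WUSS character '", ch, "' at column ", k)
    }
  }
  open_left <- unlist(stacks, use.names = FALSE)
  if (length(open_left)) {
    cp_structure_error("unclosed pair opened at column ", min(open_left))
  }
  secondary_structure(pi, pj)
}

#' Render basepairs as a WUSS string
#'
#' Mutually non-crossing pairs are rendered with `<>`; crossing pairs are
#' assigned pseudoknot letter families (`Aa`, `Bb`, ...) greedily.
#'
#' @param struct an `rna_structure`.
#' @param L alignment length (number of columns).
#' @return a WUSS string of length `L`; [pairs_from_wuss()] inverts it on the
#'   pair set.
#' @export
wuss_from_pairs <- function(struct, L) {
  stopifnot(inherits(struct, "rna_structure"))
  L <- as.integer(L)
  if (struct$B > 0 && max(struct$pairs) > L) {
    cp_structure_error("pair index exceeds alignment length ", L)
  }
  out <- rep(".", L)
  if (struct$B == 0L) return(paste(out, collapse = ""))
  fams <- list()  # each: two-column matrix of pairs in the family
  fam_of <- integer(struct$B)
  crosses <- function(p, q) (q[1] < p[1] & p[1] < q[2] & q[2] < p[2]) |
                            (p[1] < q[1] & q[1] < p[2] & p[2] < q[2])
  for (b in seq_len(struct$B)) {
    p <- struct$pairs[b, ]
    placed <- FALSE
    for (f in seq_along(fams)) {
      if (!any(apply(fams[[f]], 1L, function(q) crosses(p, q)))) {
        fams[[f]] <- rbind(fams[[f]], p)
        fam_of[b] <- f
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      if (length(fams) >= 27L) {
        cp_structure_error("more than 26 mutually crossing pseudoknot families")
      }
      fams[[length(fams) + 1L]] <- matrix(p, 1L, 2L)
      fam_of[b] <- length(fams)
    }
  }
  for (b in seq_len(struct$B)) {
    f <- fam_of[b]
    if (f == 1L) {
      out[struct$pairs[b, 1]] <- "<"
      out[struct$pairs[b, 2]] <- ">"
    } else {
      out[struct$pairs[b, 1]] <- LETTERS[f - 1L]
      out[struct$pairs[b, 2]] <- letters[f - 1L]
    }
  }
  paste(out, collapse = "")
}
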