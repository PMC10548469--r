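#' Read a crystal structure from a CIF file
#'
#' Parses the core-dictionary subset of the crystallographic information file
#' format: cell parameters, symmetry operators and the atom-site loop of the
#' first `data_` block. Standard-uncertainty suffixes such as `9.968(2)` are
#' stripped. Sites with partial occupancy are rejected (disorder is out of
#' scope). Molecular units (connected covalent components) are assigned by
#' covalent-radius bond detection on the symmetry-expanded cell.
#'
#' @param path path to a CIF file.
#' @return A `crystal_structure`: unit cell, asymmetric-unit sites, symmetry
#'   operators (identity-only if the file lists none), space-group label, and
#'   a symmetry-expanded P1 representation with molecular-unit assignments.
#' @seealso [crystal_structure()], [write_cif_p1()], [write_xyz()]
#' @export
read_cif <- function(path) {
  if (!file.exists(path)) stop("CIF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  toks <- .cif_tokenize(lines)
  # restrict to first data block
  dstart <- which(grepl("^data_", toks$value) & !toks$quoted)
  if (length(dstart) > 0) {
    from <- dstart[1]
    to <- if (length(dstart) > 1) dstart[2] - 1 else length(toks$value)
    toks <- lapply(toks, function(v) v[from:to])
  }
  fields <- .cif_parse(toks)

  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  missing <- need[!need %in% names(fields$scalars)]
  if (length(missing) > 0) {
    stop("CIF format error: missing cell parameter(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- unname(vapply(fields$scalars[need], .cif_numeric, numeric(1)))
  cell <- unit_cell(num[1], num[2], num[3], num[4], num[5], num[6])

  sg <- fields$scalars[["_symmetry_space_group_name_H-M"]]
  if (is.null(sg)) sg <- fields$scalars[["_space_group_name_H-M_alt"]]
  if (is.null(sg)) sg <- "P 1"

  ops <- .cif_symops(fields$loops)

  sites <- .cif_sites(fields$loops)
  if (nrow(sites) == 0) {
    stop("CIF format error: no atom sites found", call. = FALSE)
  }

  crystal_structure(cell = cell, sites = sites, ops = ops, spacegroup = sg)
}

# Tokenize CIF text: whitespace-separated tokens, honouring '...' and "..."
# quoting and stripping '#' comments. Multi-line ';' text fields are folded
# into single tokens (rare in core data; kept for robustness).
.cif_tokenize <- function(lines) {
  values <- character(0)
  quoted <- logical(0)
  i <- 1
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("^;", line)) {            # multi-line text field
      buf <- sub("^;", "", line)
      i <- i + 1
      while (i <= length(lines) && !grepl("^;", lines[i])) {
        buf <- paste(buf, lines[i]); i <- i + 1
      }
      values <- c(values, buf); quoted <- c(quoted, TRUE)
      i <- i + 1
      next
    }
    pos <- 1
    n <- nchar(line)
    while (pos <= n) {
      ch <- substr(line, pos, pos)
      if (grepl("^\\s$", ch)) { pos <- pos + 1; next }
      if (ch == "#") break
      if (ch == "'" || ch == '"') {
        rest <- substr(line, pos + 1, n)
        endoff <- regexpr(ch, rest, fixed = TRUE)
        if (endoff < 0) endoff <- nchar(rest) + 1
        values <- c(values, substr(rest, 1, endoff - 1))
        quoted <- c(quoted, TRUE)
        pos <- pos + 1 + endoff
      } else {
        rest <- substr(line, pos, n)
        m <- regexpr("^[^\\s]+", rest, perl = TRUE)
        tok <- regmatches(rest, m)
        values <- c(values, tok)
        quoted <- c(quoted, FALSE)
        pos <- pos + attr(m, "match.length")
      }
    }
    i <- i + 1
  }
  list(value = values, quoted = quoted)
}

# Split a token stream into scalar tag->value pairs and loop tables.
.cif_parse <- function(toks) {
  v <- toks$value; q <- toks$quoted
  scalars <- list(); loops <- list()
  i <- 1
  is_tag <- function(k) !q[k] && grepl("^_", v[k])
  is_kw  <- function(k) !q[k] && grepl("^(loop_|data_|stop_|global_)", v[k])
  while (i <= length(v)) {
    if (!q[i] && v[i] == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= length(v) && is_tag(i)) { tags <- c(tags, v[i]); i <- i + 1 }
      rows <- character(0)
      while (i <= length(v) && !is_tag(i) && !is_kw(i)) {
        rows <- c(rows, v[i]); i <- i + 1
      }
      if (length(tags) > 0) {
        ncol <- length(tags)
        nrow <- length(rows) %/% ncol
        if (nrow > 0) {
          tab <- as.data.frame(matrix(rows[seq_len(nrow * ncol)], nrow = nrow,
                                      ncol = ncol, byrow = TRUE),
                               stringsAsFactors = FALSE)
          names(tab) <- tags
          loops[[length(loops) + 1]] <- tab
        }
      }
    } else if (is_tag(i)) {
      tag <- v[i]
      if (i + 1 <= length(v)) { scalars[[tag]] <- v[i + 1]; i <- i + 2 }
      else i <- i + 1
    } else {
      i <- i + 1
    }
  }
  list(scalars = scalars, loops = loops)
}

.cif_numeric <- function(x) {
  y <- suppressWarnings(as.numeric(sub("\\(\\d+\\)$", "", x)))
  if (is.na(y)) stop("CIF format error: expected a number, got '", x, "'",
                     call. = FALSE)
  y
}

.cif_symops <- function(loops) {
  tagset <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  for (tab in loops) {
    hit <- intersect(tagset, names(tab))
    if (length(hit) > 0) {
      return(lapply(tab[[hit[1]]], parse_symop))
    }
  }
  list(parse_symop("x,y,z"))
}

.cif_sites <- function(loops) {
  for (tab in loops) {
    if (all(c("_atom_site_fract_x", "_atom_site_fract_y",
              "_atom_site_fract_z") %in% names(tab))) {
      occ <- tab[["_atom_site_occupancy"]]
      if (!is.null(occ)) {
        occv <- vapply(occ, .cif_numeric, numeric(1))
        if (any(occv < 1 - 1e-6)) {
          stop("CIF contains partially occupied site(s); ",
               "disordered structures are not supported", call. = FALSE)
        }
      }
      label <- tab[["_atom_site_label"]]
      type  <- tab[["_atom_site_type_symbol"]]
      if (is.null(label)) label <- if (is.null(type)) {
        paste0("X", seq_len(nrow(tab)))
      } else make.unique(type)
      element <- if (!is.null(type)) .element_from_symbol(type)
                 else .element_from_symbol(label)
      return(data.frame(
        label = label,
        element = element,
        fx = vapply(tab[["_atom_site_fract_x"]], .cif_numeric, numeric(1)),
        fy = vapply(tab[["_atom_site_fract_y"]], .cif_numeric, numeric(1)),
        fz = vapply(tab[["_atom_site_fract_z"]], .cif_numeric, numeric(1)),
        stringsAsFactors = FALSE, row.names = NULL))
    }
  }
  data.frame(label = character(0), element = character(0),
             fx = numeric(0), fy = numeric(0), fz = numeric(0))
}

.element_from_symbol <- function(x) {
  # 'C12', 'O1W', 'Na+', 'S2-' -> element symbol; keep two-letter symbols intact
  core <- sub("[^A-Za-z].*$", "", x)
  two <- substr(paste0(toupper(substr(core, 1, 1)),
                       tolower(substr(core, 2, 2))), 1, 2)
  one <- toupper(substr(core, 1, 1))
  ifelse(two %in% .pt$symbol, two, one)
}

#' Parse a symmetry operator string
#'
#' Converts a CIF operator such as `"-x, y+1/2, -z"` into a fractional
#' rotation matrix and translation vector.
#'
#' @param s operator string, three comma-separated components in x, y, z.
#' @return list with `R` (3x3 integer-valued matrix) and `t` (length-3
#'   translation, fractional).
#' @export
parse_symop <- function(s) {
  comps <- strsplit(gsub("[[:space:]]", "", s), ",", fixed = TRUE)[[1]]
  if (length(comps) != 3) {
    stop("unparseable symmetry operator '", s, "'", call. = FALSE)
  }
  R <- matrix(0, 3, 3)
  tvec <- numeric(3)
  for (i in 1:3) {
    comp <- comps[i]
    terms <- regmatches(comp, gregexpr("[+-]?[^+-]+", comp))[[1]]
    if (length(terms) == 0 || paste(terms, collapse = "") != comp) {
      stop("unparseable symmetry operator '", s, "'", call. = FALSE)
    }
    for (term in terms) {
      sign <- if (substr(term, 1, 1) == "-") -1 else 1
      body <- sub("^[+-]", "", term)
      axis <- regmatches(body, regexpr("[xyzXYZ]", body))
      if (length(axis) == 1) {
        coef <- sub("[xyzXYZ]", "", body)
        coef <- sub("\\*$", "", coef)
        cval <- if (coef == "") 1 else .parse_fraction(coef, s)
        j <- match(tolower(axis), c("x", "y", "z"))
        R[i, j] <- R[i, j] + sign * cval
      } else {
        tvec[i] <- tvec[i] + sign * .parse_fraction(body, s)
      }
    }
  }
  list(R = R, t = tvec)
}

.parse_fraction <- function(x, op) {
  if (grepl("^\\d+/\\d+$", x)) {
    p <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
    return(p[1] / p[2])
  }
  y <- suppressWarnings(as.numeric(x))
  if (is.na(y)) stop("unparseable symmetry operator '", op, "'", call. = FALSE)
  y
}

#' Write a body or expanded structure as XYZ
#'
#' @param x a `body`, or a `crystal_structure` (its expanded P1 cell is
#'   written in Cartesian coordinates).
#' @param path output file.
#' @param comment second-line comment.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment = "") {
  at <- if (inherits(x, "body")) x$atoms else expand_structure(x)$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(at)), comment), con)
  writeLines(sprintf("%-2s %14.8f %14.8f %14.8f",
                     at$element, at$x, at$y, at$z), con)
  invisible(path)
}

#' Write a structure as a P1 CIF
#'
#' The symmetry-expanded cell is written with identity symmetry only, so any
#' CIF-aware program can reread it without space-group support.
#'
#' @param structure a `crystal_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cif_p1 <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  exp <- expand_structure(structure)
  cell <- structure$cell
  at <- exp$atoms
  frac <- cart_to_frac(cell, as.matrix(at[, c("x", "y", "z")]))
  frac <- frac - floor(frac)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "data_synthsearch",
    sprintf("_cell_length_a    %.6f", cell$a),
    sprintf("_cell_length_b    %.6f", cell$b),
    sprintf("_cell_length_c    %.6f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta  %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma),
    "_symmetry_space_group_name_H-M 'P 1'",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z"), con)
  writeLines(sprintf("%s %s %12.8f %12.8f %12.8f",
                     make.unique(paste0(at$element, seq_len(nrow(at)))),
                     at$element, frac[, 1], frac[, 2], frac[, 3]), con)
  invisible(path)
}
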