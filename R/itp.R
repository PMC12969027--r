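#' Write a topology in GROMACS ITP dialect
#'
#' Emits `[moleculetype]`, `[atoms]`, `[bonds]` (funct 1), `[angles]`,
#' `[dihedrals]` and `[exclusions]` sections. Go contacts, if present, are
#' written to a separate include file (`<path base>_go.itp`) as
#' `[pairs]`-style rows `i j funct sigma epsilon` (funct 1, LJ with the
#' well minimum at the native distance). Output is deterministic:
#' byte-identical for identical input.
#'
#' @param top a `cg_topology`
#' @param path output .itp path
#' @param go_path path for the Go include; default derived from `path`;
#'   ignored when the topology has no Go contacts
#' @return `path` invisibly
#' @export
write_itp <- function(top, path, go_path = NULL) {
  validate_topology(top)
  ln <- character(0)
  add <- function(...) ln <<- c(ln, ...)
  add("; Martini 3 topology written by collagencg", "",
      "[ moleculetype ]", "; name  nrexcl", sprintf("%s  1", top$molecule_name), "")
  add("[ atoms ]", ";  nr  type  resnr  residue  atom  cgnr  charge  mass")
  b <- top$beads
  resno <- if ("res_index" %in% names(b)) b$res_index else rep(1L, nrow(b))
  for (r in seq_len(nrow(b))) {
    add(sprintf("%5d %6s %5d %6s %5s %5d %9.3f %9.3f",
                b$index[r], b$bead_type[r], resno[r], b$residue[r],
                b$name[r], b$index[r], b$charge[r], b$mass[r]))
  }
  add("")
  if (nrow(top$bonds) > 0L) {
    add("[ bonds ]", ";  i  j  funct  length  k")
    for (r in seq_len(nrow(top$bonds))) {
      add(sprintf("%5d %5d %5d %10.4f %12.1f",
                  top$bonds$i[r], top$bonds$j[r], top$bonds$funct[r],
                  top$bonds$eq_value[r], top$bonds$force_constant[r]))
    }
    add("")
  }
  if (nrow(top$angles) > 0L) {
    add("[ angles ]", ";  i  j  k  funct  angle  k")
    for (r in seq_len(nrow(top$angles))) {
      add(sprintf("%5d %5d %5d %5d %10.2f %12.2f",
                  top$angles$i[r], top$angles$j[r], top$angles$k[r],
                  top$angles$funct[r], top$angles$eq_value[r],
                  top$angles$force_constant[r]))
    }
    add("")
  }
  if (nrow(top$dihedrals) > 0L) {
    add("[ dihedrals ]", ";  i  j  k  l  funct  angle  k  mult")
    for (r in seq_len(nrow(top$dihedrals))) {
      add(sprintf("%5d %5d %5d %5d %5d %10.2f %12.2f %5d",
                  top$dihedrals$i[r], top$dihedrals$j[r], top$dihedrals$k[r],
                  top$dihedrals$l[r], top$dihedrals$funct[r],
                  top$dihedrals$eq_value[r], top$dihedrals$force_constant[r], 1L))
    }
    add("")
  }
  if (nrow(top$exclusions) > 0L) {
    add("[ exclusions ]")
    for (r in seq_len(nrow(top$exclusions))) {
      add(sprintf("%5d %5d", top$exclusions$i[r], top$exclusions$j[r]))
    }
    add("")
  }
  writeLines(ln, path)
  if (nrow(top$go_contacts) > 0L) {
    if (is.null(go_path)) {
      go_path <- sub("\\.itp$", "", path)
      go_path <- paste0(go_path, "_go.itp")
    }
    gl <- c("; Go contact pairs (LJ minimum at native distance)",
            "[ pairs ]", ";  i  j  funct  sigma  epsilon")
    g <- top$go_contacts
    for (r in seq_len(nrow(g))) {
      gl <- c(gl, sprintf("%5d %5d %5d %12.6f %12.6f",
                          g$i[r], g$j[r], 1L, g$sigma_lj[r], g$epsilon[r]))
    }
    writeLines(gl, go_path)
  }
  invisible(path)
}

.itp_sections <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- NULL
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^\\[\\s*(\\S+)\\s*\\]$", l))[[1]]
    if (length(m) == 2L) {
      sec <- m[2]
      if (is.null(out[[sec]])) out[[sec]] <- character(0)
    } else if (!is.null(sec)) {
      out[[sec]] <- c(out[[sec]], l)
    }
  }
  out
}

#' Parse a GROMACS ITP file written by [write_itp()]
#'
#' @param path .itp file path
#' @param go_path optional Go include to merge back in
#' @return a `cg_topology`
#' @export
read_itp <- function(path, go_path = NULL) {
  sec <- .itp_sections(readLines(path))
  tok <- function(lines) lapply(strsplit(lines, "\\s+"), identity)
  mol <- strsplit(sec$moleculetype[1], "\\s+")[[1]][1]
  at <- do.call(rbind, lapply(tok(sec$atoms), function(t) {
    data.frame(index = as.integer(t[1]), bead_type = t[2],
               res_index = as.integer(t[3]), residue = t[4], name = t[5],
               charge = as.numeric(t[7]), mass = as.numeric(t[8]),
               stringsAsFactors = FALSE)
  }))
  parse_terms <- function(lines, nidx) {
    if (is.null(lines)) return(NULL)
    do.call(rbind, lapply(tok(lines), function(t) {
      idx <- as.integer(t[seq_len(nidx)])
      df <- as.data.frame(as.list(idx))
      names(df) <- c("i", "j", "k", "l")[seq_len(nidx)]
      df$funct <- as.integer(t[nidx + 1])
      df$eq_value <- as.numeric(t[nidx + 2])
      df$force_constant <- as.numeric(t[nidx + 3])
      df
    }))
  }
  bonds <- parse_terms(sec$bonds, 2L)
  angles <- parse_terms(sec$angles, 3L)
  dihedrals <- parse_terms(sec$dihedrals, 4L)
  exclusions <- if (!is.null(sec$exclusions)) {
    do.call(rbind, lapply(tok(sec$exclusions), function(t) {
      data.frame(i = as.integer(t[1]), j = as.integer(t[2]))
    }))
  } else NULL
  go <- NULL
  if (!is.null(go_path) && file.exists(go_path)) {
    gsec <- .itp_sections(readLines(go_path))
    go <- do.call(rbind, lapply(tok(gsec$pairs), function(t) {
      data.frame(i = as.integer(t[1]), j = as.integer(t[2]),
                 sigma_lj = as.numeric(t[4]), epsilon = as.numeric(t[5]))
    }))
    go$r_native <- go$sigma_lj * 2^(1 / 6)
    go <- go[, c("i", "j", "r_native", "sigma_lj", "epsilon")]
  }
  cg_topology(mol, at, bonds = bonds, angles = angles, dihedrals = dihedrals,
              exclusions = exclusions, go_contacts = go)
}

#' Dump a topology as JSON
#'
#' @param top a `cg_topology`
#' @param path output path
#' @return `path` invisibly
#' @export
write_topology_json <- function(top, path) {
  jsonlite::write_json(unclass(top), path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
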