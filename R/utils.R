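# Internal helpers: condition constructors and misc utilities.

data_error <- function(msg, class = "rpfdp_data_error") {
  stop(structure(
    class = c(class, "rpfdp_data_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

usage_error <- function(msg) {
  stop(structure(
    class = c("rpfdp_usage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

named_warning <- function(msg, class) {
  warning(structure(
    class = c(class, "rpfdp_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable key for one atom; used for set comparisons across conformers.
atom_key <- function(chain, resno, atom) paste(chain, resno, atom, sep = ".")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

check_resname <- function(resname) {
  bad <- setdiff(unique(resname), AA3)
  if (length(bad) > 0L)
    data_error(sprintf("unknown residue type(s): %s", paste(bad, collapse = ", ")),
               class = "rpfdp_unknown_residue")
  invisible(TRUE)
}

# Derive a per-seed stream without consuming the global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
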