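# Cytosine base editor targeting rules: PAM pattern and side, spacer
# length, editing window, and context preference. 13 built-in presets plus
# full customization from YAML/JSON config files.

IUPAC_CLASSES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Construct a cytosine base editor model
#'
#' Editing-window positions are counted 1-based from the 5' end of the
#' protospacer as written 5'->3'. For 3'-PAM (Cas9-family) editors position
#' 1 is the PAM-distal base; for 5'-PAM (Cas12a) editors it is the
#' PAM-proximal base. This is the convention under which "position 6" for
#' YEE-BE3 is standard, and it applies uniformly to both PAM sides.
#'
#' @param name Editor name.
#' @param pam_pattern IUPAC degenerate PAM string, e.g. `"NGG"`, `"TTTV"`.
#' @param pam_side `"3prime"` or `"5prime"`, the side of the PAM relative to
#'   the protospacer.
#' @param spacer_len Protospacer length in nt.
#' @param window_start,window_end Inclusive editing-window bounds,
#'   `1 <= window_start <= window_end <= spacer_len`.
#' @param context_order Ranked 5'-dinucleotide context preference for the
#'   edited C (best first). Default `TC > CC > AC > GC`.
#' @return An object of class `cbe_model`.
#' @examples
#' cbe_model("my-editor", "NGN", "3prime", 20, 4, 8)
#' @export
cbe_model <- function(name, pam_pattern, pam_side = c("3prime", "5prime"),
                      spacer_len, window_start, window_end,
                      context_order = c("TC", "CC", "AC", "GC")) {
  pam_side <- match.arg(pam_side)
  pam_pattern <- toupper(pam_pattern)
  spacer_len <- as.integer(spacer_len)
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  if (nchar(pam_pattern) == 0L) stop("pam_pattern must be non-empty", call. = FALSE)
  bad <- setdiff(strsplit(pam_pattern, "")[[1]], names(IUPAC_CLASSES))
  if (length(bad) > 0) {
    stop("illegal IUPAC letter '", bad[1], "' in PAM pattern '", pam_pattern, "'",
         call. = FALSE)
  }
  if (!(window_start >= 1L && window_start <= window_end && window_end <= spacer_len)) {
    stop("editing window must satisfy 1 <= window_start <= window_end <= spacer_len",
         call. = FALSE)
  }
  structure(
    list(name = name, pam_pattern = pam_pattern, pam_side = pam_side,
         spacer_len = spacer_len, window_start = window_start,
         window_end = window_end, context_order = toupper(context_order)),
    class = "cbe_model"
  )
}

#' @export
print.cbe_model <- function(x, ...) {
  side <- if (x$pam_side == "3prime") "3'" else "5'"
  cat(sprintf("<cbe_model> %s: PAM %s (%s of spacer), spacer %d nt, window %d-%d\n",
              x$name, x$pam_pattern, side, x$spacer_len,
              x$window_start, x$window_end))
  invisible(x)
}

preset_registry <- function() {
  if (is.null(.cbei_env$presets)) {
    path <- system.file("extdata", "cbe_presets.json", package = "cbei")
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    presets <- lapply(raw$presets, function(p) {
      cbe_model(p$name, p$pam_pattern, p$pam_side, p$spacer_len,
                p$window_start, p$window_end)
    })
    names(presets) <- vapply(presets, function(p) p$name, character(1))
    .cbei_env$presets <- presets
  }
  .cbei_env$presets
}

#' List built-in CBE preset names
#'
#' @return Character vector of the 13 built-in editor names.
#' @export
list_presets <- function() {
  names(preset_registry())
}

# canonical key for alias-insensitive preset lookup
preset_key <- function(name) {
  gsub("[^a-z0-9]", "", tolower(name))
}

#' Load a built-in CBE preset
#'
#' Lookup is alias-insensitive: case, hyphens, parentheses and spaces are
#' ignored, so `"target aid ng"` and `"Target-AID-NG"` are equivalent.
#'
#' @param name Preset name, one of [list_presets()].
#' @return A `cbe_model`.
#' @examples
#' load_preset("YEE-BE3")
#' @export
load_preset <- function(name) {
  reg <- preset_registry()
  hit <- match(preset_key(name), vapply(names(reg), preset_key, character(1)))
  if (is.na(hit)) {
    stop("unknown CBE preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[hit]]
}

#' Load a custom CBE model from a YAML or JSON config file
#'
#' The file must provide the fields `name`, `pam_pattern`, `pam_side`,
#' `spacer_len`, `window_start`, `window_end`, and may provide
#' `context_order`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cbe_model`.
#' @export
read_cbe_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  need <- c("name", "pam_pattern", "pam_side", "spacer_len",
            "window_start", "window_end")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    stop("CBE config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ctx <- if (!is.null(cfg$context_order)) cfg$context_order else c("TC", "CC", "AC", "GC")
  cbe_model(cfg$name, cfg$pam_pattern, cfg$pam_side, cfg$spacer_len,
            cfg$window_start, cfg$window_end, context_order = ctx)
}

#' Compile an IUPAC pattern into a matcher
#'
#' The matcher accepts exactly the concrete `{A,C,G,T}` expansions of the
#' degenerate pattern; strings containing `N` never match (a genomic `N`
#' cannot satisfy any PAM letter, including pattern letter `N`).
#'
#' @param pattern IUPAC degenerate DNA string.
#' @return An object of class `pam_matcher` with a compiled anchored regex.
#' @examples
#' m <- iupac_to_matcher("NGG")
#' pam_matches(m, c("AGG", "AGA"))
#' @export
iupac_to_matcher <- function(pattern) {
  pattern <- toupper(pattern)
  letters <- strsplit(pattern, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_CLASSES))
  if (length(bad) > 0) {
    stop("illegal IUPAC letter '", bad[1], "' in pattern '", pattern, "'",
         call. = FALSE)
  }
  classes <- vapply(letters, function(l) {
    opts <- IUPAC_CLASSES[[l]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1))
  structure(
    list(pattern = pattern,
         regex = paste0(classes, collapse = ""),
         anchored = paste0("^", paste0(classes, collapse = ""), "$"),
         width = length(letters)),
    class = "pam_matcher"
  )
}

#' Test concrete strings against a PAM matcher
#'
#' @param matcher A `pam_matcher` from [iupac_to_matcher()].
#' @param x Character vector of concrete DNA strings.
#' @return Logical vector; `TRUE` where `x` is a concrete expansion of the
#'   pattern.
#' @export
pam_matches <- function(matcher, x) {
  stopifnot(inherits(matcher, "pam_matcher"))
  grepl(matcher$anchored, x)
}

#' Editing-window positions of a model
#'
#' @param model A `cbe_model`.
#' @return Integer vector `window_start:window_end`, positions counted
#'   1-based from the 5' end of the protospacer.
#' @export
window_positions <- function(model) {
  stopifnot(inherits(model, "cbe_model"))
  seq.int(model$window_start, model$window_end)
}
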