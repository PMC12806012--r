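# internal helpers shared across modules

# stable content hash of an arbitrary R object
obj_hash <- function(x) rlang::hash(x)

# derive a per-stage seed from a global seed so adding a stage never shifts
# another stage's randomness; result stays inside 32-bit integer range
derive_seed <- function(seed, stage) {
  h <- rlang::hash(paste0("tspe::", stage))
  off <- strtoi(substr(h, 1, 6), base = 16L)
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483629) + 1L
}

read_table_lines <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  which_keep <- nzchar(lines)
  list(lines = lines[which_keep], line_no = which(which_keep))
}

split_fields <- function(lines) strsplit(lines, "[ \t]+")
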