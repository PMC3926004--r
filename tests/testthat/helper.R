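# small fixtures built in code

# a bare structure with explicitly placed atoms
make_structure <- function(xyz, elements = "C", cell = unit_cell(10, 12, 14),
                           sg = "P1", b = 0, resno = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  at <- data.frame(resno = resno %||% seq_len(n), resid = "TOY",
                   elety = paste0("C", seq_len(n)),
                   element = rep(elements, length.out = n),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occ = 1, b = rep(b, length.out = n),
                   stringsAsFactors = FALSE)
  xtal_structure(cell, sg, at)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# total electron count of a structure's full cell content
cell_electrons <- function(s) {
  nops <- if (s$sg$name == "P1") 1 else s$sg$n_ops
  sum(sapply(s$atoms$element, electron_count)) * nops
}

res_sel <- function(tpl, resno, names) {
  which(tpl$atoms$resno == resno & tpl$atoms$elety %in% names)
}
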