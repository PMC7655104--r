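# bind a list of same-shaped record lists into a data frame in one pass
# (avoids per-row data.frame() overhead in event-ledger accumulation)
.bind_records <- function(rows, template) {
  if (!length(rows)) return(template)
  cols <- names(rows[[1L]])
  out <- lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}
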