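# Synthetic example of a cancer-implicated miRNA exclusion list
# (one ID per line; comments allowed). Assemble a real list from your own
# literature curation.
miR-21
miR-155
miR-17
miR-221  # oncomiR cluster member
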