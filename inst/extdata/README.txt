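published_range_change_envthin.csv
  Published per-GCM range-change percentages for the fly orchid
  (Ophrys insectifera) EnvThin ensemble: area loss, area gain, overall
  change and current occurrences lost, for three GCMs (BC, MI, MR), two
  SSPs and two future time slices. Used as *input* to verify the
  package's scenario-aggregation arithmetic (per-SSP/time-slice means
  across GCMs and the gain - loss = overall identity). These values are
  published results of an external analysis, not output of this package.

published_reference_means.csv
  The corresponding published per-group (SSP x time slice) mean
  percentages, used as the comparison values for the aggregation check.
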