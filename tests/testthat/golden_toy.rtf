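{\rtf1\ansi\deff0
{\fonttbl{\f0 Times New Roman;}}
\fs20
{\pard\b toy\b0\par}
\trowd\trgaph108\cellx1387\clmgf\cellx2427\clmrg\cellx3467\clmgf\cellx4507\clmrg\cellx5547\clmgf\cellx6587\clmrg\cellx7627\clmrg\cellx9360\pard\intbl\qc \b \cell\b a1\cell\b \cell\b a2\cell\b \cell\b P-value\cell\b \cell\b \cell\row
\trowd\trgaph108\cellx1387\cellx2427\cellx3467\cellx4507\cellx5547\cellx6587\cellx7627\cellx9360\pard\intbl\qc \b Variable\cell\b b1\cell\b b2\cell\b b1\cell\b b2\cell\b A\cell\b B\cell\b A \u215? B\cell\row
\trowd\trgaph108\cellx1387\cellx2427\cellx3467\cellx4507\cellx5547\cellx6587\cellx7627\cellx9360\pard\intbl\qc y\cell2 \u177? 1\cell3 \u177? 1\cell6 \u177? 1\cell7 \u177? 1\cell0.016\cell0.374\cell1\cell\row
{\pard Values are means \u177? SEM, n = 2 per treatment group. A \u215? B = A \u215? B interaction effect.\par}
{\pard\par}
}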