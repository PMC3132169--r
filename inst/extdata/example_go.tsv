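bes_id	go_id	namespace	top_level_term
readA.F	GO:0003824	molecular_function	catalytic_activity
readA.F	GO:0005488	molecular_function	binding
readA.R	GO:0005488	molecular_function	binding
readB.F	GO:0008152	biological_process	metabolic_process
readB.F	GO:0009987	biological_process	cellular_process
readB.R	GO:0005488	molecular_function	binding
readC.F	GO:0051179	biological_process	localization
readC.F	GO:0005575	cellular_component	cell_part
readD.F	GO:0003824	molecular_function	catalytic_activity
readD.F	GO:0008152	biological_process	metabolic_process
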