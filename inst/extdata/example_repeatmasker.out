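   SW  perc perc perc  query     position in query    matching  repeat         position in repeat
score  div. del. ins.  sequence  begin  end   (left)  repeat    class/family   begin  end (left)  ID
--------------------------------------------------------------------------------------------------
  453  12.1  0.5  0.8  readA.F     101   350   (249)  +  RE-1      LTR/Copia        1   250   (0)    1
  287  18.4  1.2  0.0  readB.F      12   140   (460)  C  LINE-2    LINE/L1        310   438  (62)    2
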