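{"type":"Polygon","coordinates":[[[-60,5],[-30,5],[-32,-5],[-34,-12],[-36,-18],[-38,-22],[-40,-25],[-44,-30],[-48,-35],[-52,-40],[-70,-40],[-70,5],[-60,5]]]}
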