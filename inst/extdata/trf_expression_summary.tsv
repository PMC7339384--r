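label	c1d_rpm	a1d_rpm
ENSRNA049443699:1-20	30155.81	24539.08
down_regulated_total	33315.52	26572.77
up_regulated_total	663.41	840.83
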