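model,day,animal_rank,rc_value,pi_width_95,ci_width_95,flagged_misprint
CBC,7,1,1.73,1.9,0.39,FALSE
CBC,7,2,2.56,1.89,0.32,FALSE
CBC,7,3,2.93,1.9,0.3,FALSE
CBC,7,4,2.78,1.9,0.6,FALSE
CBC,7,5,3.17,1.89,0.63,FALSE
CBC,7,6,2.09,1.88,0.33,FALSE
CBC,7,7,2.57,1.89,0.33,FALSE
CBC,7,8,3.16,1.93,0.37,FALSE
CBC,10,1,3.33,1.89,0.35,FALSE
CBC,10,2,3.31,1.89,0.39,FALSE
CBC,10,3,3.5,1.9,0.53,FALSE
CBC,10,4,2.24,1.9,0.35,FALSE
CBC,10,5,2.78,1.9,0.39,FALSE
CBC,10,6,3.18,1.89,0.37,FALSE
CBC,10,7,3.48,1.9,0.36,FALSE
CBC,10,8,3.48,1.9,0.38,FALSE
CBC,14,1,3.3,1.89,0.49,FALSE
CBC,14,2,1.9,1.9,0.37,FALSE
CBC,14,3,2.7,1.9,0.37,FALSE
CBC,14,4,3.14,1.9,0.36,FALSE
CBC,14,5,3.43,1.89,0.37,FALSE
CBC,14,6,3.77,1.89,0.38,FALSE
CBC,14,7,4.02,1.89,0.46,FALSE
CBC,17,1,2,1.89,0.33,FALSE
CBC,17,2,2.66,1.9,0.35,FALSE
CBC,17,3,3.06,1.9,0.34,FALSE
CBC,17,4,2.97,1.89,0.33,FALSE
CBC,17,5,2.86,1.89,0.52,FALSE
CBC,17,6,3.41,1.89,0.49,FALSE
CBC,17,7,1.91,1.89,0.28,FALSE
CBC,21,1,2.55,1.96,0.32,FALSE
CBC,21,2,3.1,1.9,0.34,FALSE
CBC,21,3,3.28,1.9,0.32,FALSE
CBC,21,4,2.87,1.9,0.46,FALSE
CBC,21,5,2.25,1.94,0.87,FALSE
CBC,21,6,2.14,1.92,0.33,FALSE
CBC,21,7,2.73,2.01,0.38,FALSE
CBC,21,8,3.06,1.94,0.33,FALSE
CBC,25,1,3.12,1.94,0.34,FALSE
CBC,25,2,2.65,1.94,0.75,FALSE
CBC,25,3,3.15,1.93,0.55,FALSE
CBC,25,4,2.21,1.92,0.48,FALSE
CBC,25,5,2.68,1.93,0.36,FALSE
CBC,25,6,3.07,20.6,0.33,TRUE
CBC,25,7,2.32,1.94,0.55,FALSE
CBC,25,8,2.97,1.99,0.69,FALSE
CBC_SCHEM,7,1,2.26,1.76,0.63,FALSE
CBC_SCHEM,7,2,2.54,1.7,0.39,FALSE
CBC_SCHEM,7,3,2.72,1.88,0.33,FALSE
CBC_SCHEM,7,4,2.85,1.67,0.54,FALSE
CBC_SCHEM,7,5,3.2,1.68,0.57,FALSE
CBC_SCHEM,7,6,2.48,1.99,0.44,FALSE
CBC_SCHEM,7,7,2.34,1.68,0.39,FALSE
CBC_SCHEM,7,8,3,1.84,0.42,FALSE
CBC_SCHEM,10,1,3.16,1.68,0.41,FALSE
CBC_SCHEM,10,2,3.22,1.68,0.36,FALSE
CBC_SCHEM,10,3,3.48,1.68,0.54,FALSE
CBC_SCHEM,10,4,3.08,1.68,0.93,FALSE
CBC_SCHEM,10,5,2.67,1.68,0.37,FALSE
CBC_SCHEM,10,6,3.06,1.68,0.35,FALSE
CBC_SCHEM,10,7,3.47,1.68,0.37,FALSE
CBC_SCHEM,10,8,3.43,1.72,0.37,FALSE
CBC_SCHEM,14,1,3.22,1.67,0.46,FALSE
CBC_SCHEM,14,2,1.96,1.69,0.33,FALSE
CBC_SCHEM,14,3,2.54,1.68,0.36,FALSE
CBC_SCHEM,14,4,2.99,1.68,0.36,FALSE
CBC_SCHEM,14,5,3.13,1.67,0.41,FALSE
CBC_SCHEM,14,6,3.76,1.74,0.36,FALSE
CBC_SCHEM,14,7,3.79,1.68,0.46,FALSE
CBC_SCHEM,17,1,2.28,1.69,0.37,FALSE
CBC_SCHEM,17,2,2.46,1.68,0.35,FALSE
CBC_SCHEM,17,3,2.86,1.69,0.34,FALSE
CBC_SCHEM,17,4,2.81,1.67,0.32,FALSE
CBC_SCHEM,17,5,2.86,1.68,0.47,FALSE
CBC_SCHEM,17,6,3.38,1.67,0.45,FALSE
CBC_SCHEM,17,7,2.87,1.72,1.13,FALSE
CBC_SCHEM,21,1,2.4,1.73,0.39,FALSE
CBC_SCHEM,21,2,3.27,1.68,0.58,FALSE
CBC_SCHEM,21,3,3.45,1.68,0.37,FALSE
CBC_SCHEM,21,4,3.04,1.68,0.74,FALSE
CBC_SCHEM,21,5,2.51,1.7,0.86,FALSE
CBC_SCHEM,21,6,2.4,1.8,0.37,FALSE
CBC_SCHEM,21,7,2.48,1.77,0.39,FALSE
CBC_SCHEM,21,8,2.77,1.73,0.37,FALSE
CBC_SCHEM,25,1,2.99,1.74,0.34,FALSE
CBC_SCHEM,25,2,2.59,1.72,0.68,FALSE
CBC_SCHEM,25,3,3.09,1.7,0.52,FALSE
CBC_SCHEM,25,4,2.83,1.7,0.84,FALSE
CBC_SCHEM,25,5,2.69,1.7,0.54,FALSE
CBC_SCHEM,25,6,3.42,1.85,0.53,FALSE
CBC_SCHEM,25,7,2.37,1.72,0.55,FALSE
CBC_SCHEM,25,8,3.07,1.76,0.63,FALSE
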